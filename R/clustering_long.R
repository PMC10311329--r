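# Long-read clustering: DBSCAN over an epsilon ladder on the L2-normalized
# embeddings, then greedy marker-scored integration of all runs. At each
# contamination level of the ladder the best-F1 candidate bin below the level
# is emitted and its contigs removed from every other candidate, until no
# qualifying candidate remains; the ladder then relaxes.

DEFAULT_EPS_LADDER <- c(0.01, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4,
                        0.45, 0.5, 0.55)
DEFAULT_CONT_LADDER <- c(0.1, 0.2, 0.3, 0.4, 0.5, 1)

l2_normalize_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  X / ifelse(nrm > 0, nrm, 1)
}

# Classic DBSCAN on a precomputed distance matrix. A point is core when its
# eps-neighbourhood (self included) holds at least min_pts points; clusters
# are the connected components of core points under eps-reachability, with
# border points attached to the first cluster that reaches them. Labels:
# 0 = noise, 1..k = clusters. Deterministic (seed order of expansion).
dbscan_labels <- function(D, eps, min_pts) {
  n <- nrow(D)
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nbrs) >= min_pts
  labels <- integer(n) # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- setdiff(nbrs[[i]], i)
    while (length(frontier) > 0L) {
      j <- frontier[1L]
      frontier <- frontier[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) {
          frontier <- c(frontier, setdiff(nbrs[[j]], which(labels != 0L)))
        }
      }
    }
  }
  labels
}

#' DBSCAN sweep over an epsilon ladder
#'
#' Embedding rows are L2-normalized so Euclidean distances live on a bounded
#' scale matching the fixed ladder, then DBSCAN is run once per epsilon.
#'
#' @param embeddings Embedding matrix (rownames = contig ids).
#' @param eps_list Increasing positive epsilon values (default the 12-value
#'   ladder 0.01, 0.05, ..., 0.55).
#' @param min_samples Minimum neighbourhood size for a core point (default 5).
#' @return Object of class `dbscan_sweep`: list of runs, each with `eps`,
#'   `labels` (named integer vector; 0 = noise) and `noise` (ids).
#' @export
dbscan_sweep <- function(embeddings, eps_list = DEFAULT_EPS_LADDER,
                         min_samples = 5L) {
  stopifnot(length(eps_list) > 0L, all(eps_list > 0),
            !is.unsorted(eps_list, strictly = TRUE))
  X <- l2_normalize_rows(as.matrix(embeddings))
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  D <- as.matrix(dist(X))
  runs <- lapply(eps_list, function(eps) {
    labels <- dbscan_labels(D, eps, min_samples)
    names(labels) <- ids
    list(eps = eps, labels = labels, noise = ids[labels == 0L])
  })
  structure(list(runs = runs, ids = ids), class = "dbscan_sweep")
}

# Candidate bins of one sweep: every DBSCAN cluster of every run, plus each
# noise point as a singleton candidate (a single-contig genome must be able
# to win selection).
candidate_bins <- function(sweep, noise_singletons = TRUE) {
  cands <- list()
  for (ri in seq_along(sweep$runs)) {
    run <- sweep$runs[[ri]]
    labs <- run$labels
    for (cl in setdiff(unique(labs), 0L)) {
      cands[[length(cands) + 1L]] <-
        list(run = ri, label = cl, contigs = names(labs)[labs == cl])
    }
    if (noise_singletons) {
      for (id in run$noise) {
        cands[[length(cands) + 1L]] <-
          list(run = ri, label = 0L, contigs = id)
      }
    }
  }
  cands
}

#' Greedy marker-scored integration of DBSCAN runs
#'
#' Iterates the contamination ladder; at each level the candidate bin with
#' the highest marker F1 among those with contamination below the level is
#' emitted, its contigs are removed from all other candidates, and the
#' affected candidates are rescored, until no candidate below the level
#' remains. Candidates without marker hits (F1 = 0) are never emitted. Ties
#' on F1 break to the larger total length, then the lexicographically
#' smallest contig id.
#'
#' @param sweep A [dbscan_sweep()] result (or a plain list of candidate bins,
#'   each a character vector of contig ids).
#' @param annotation A `marker_annotation`.
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param cont_ladder Nondecreasing contamination thresholds ending at 1.
#' @return List of selected bins: each has `contigs`, `score`
#'   (`quality_score` at selection time) and `cont_level`.
#' @export
ensemble_select <- function(sweep, annotation, contig_lengths,
                            cont_ladder = DEFAULT_CONT_LADDER) {
  stopifnot(!is.unsorted(cont_ladder), cont_ladder[length(cont_ladder)] == 1)
  cands <- if (inherits(sweep, "dbscan_sweep")) {
    lapply(candidate_bins(sweep), `[[`, "contigs")
  } else {
    sweep
  }
  cands <- cands[lengths(cands) > 0L]
  scores <- lapply(cands, score_bin, annotation = annotation)
  selected <- list()
  for (cont in cont_ladder) {
    repeat {
      best <- 0L
      for (i in seq_along(cands)) {
        s <- scores[[i]]
        if (length(cands[[i]]) == 0L || s$f1 <= 0 || s$contamination >= cont) next
        if (best == 0L) { best <- i; next }
        b <- scores[[best]]
        if (s$f1 > b$f1) { best <- i; next }
        if (s$f1 < b$f1) next
        li <- sum(contig_lengths[cands[[i]]])
        lb <- sum(contig_lengths[cands[[best]]])
        if (li > lb || (li == lb && min(cands[[i]]) < min(cands[[best]]))) {
          best <- i
        }
      }
      if (best == 0L) break
      bin <- cands[[best]]
      selected[[length(selected) + 1L]] <-
        list(contigs = bin, score = scores[[best]], cont_level = cont)
      for (i in seq_along(cands)) {
        if (length(cands[[i]]) == 0L) next
        kept <- setdiff(cands[[i]], bin)
        if (length(kept) != length(cands[[i]])) {
          cands[[i]] <- kept
          scores[[i]] <- score_bin(kept, annotation)
        }
      }
      cands[[best]] <- character(0)
    }
  }
  selected
}

#' Resolve contigs left unselected by the ensemble
#'
#' @param selected Output of [ensemble_select()].
#' @param all_ids All contig ids under consideration.
#' @param contig_lengths Named numeric vector of lengths.
#' @param emit_leftover If TRUE, every unselected contig at least
#'   `min_bin_size` bp long becomes a singleton bin; otherwise leftovers are
#'   reported unbinned.
#' @param min_bin_size Output bin size threshold (bp).
#' @return List with `bins` (list of contig-id vectors) and `unbinned`
#'   (character vector).
#' @export
handle_noise <- function(selected, all_ids, contig_lengths,
                         emit_leftover = FALSE, min_bin_size = 200000) {
  bins <- lapply(selected, `[[`, "contigs")
  leftover <- setdiff(all_ids, unlist(bins, use.names = FALSE))
  if (emit_leftover) {
    promote <- leftover[contig_lengths[leftover] >= min_bin_size]
    bins <- c(bins, as.list(promote))
    leftover <- setdiff(leftover, promote)
  }
  list(bins = bins, unbinned = leftover)
}

#' Long-read clustering of embedded contigs
#'
#' @inheritParams dbscan_sweep
#' @inheritParams ensemble_select
#' @inheritParams handle_noise
#' @return Named character vector contig id -> bin id (unselected contigs
#'   absent).
#' @export
cluster_long <- function(embeddings, annotation, contig_lengths,
                         eps_list = DEFAULT_EPS_LADDER, min_samples = 5L,
                         cont_ladder = DEFAULT_CONT_LADDER,
                         emit_leftover = FALSE, min_bin_size = 200000) {
  sweep <- dbscan_sweep(embeddings, eps_list, min_samples)
  selected <- ensemble_select(sweep, annotation, contig_lengths, cont_ladder)
  final <- handle_noise(selected, rownames(embeddings), contig_lengths,
                        emit_leftover, min_bin_size)
  assignment <- rep(sprintf("bin_%04d", seq_along(final$bins)),
                    lengths(final$bins))
  setNames(assignment, unlist(final$bins, use.names = FALSE))
}
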