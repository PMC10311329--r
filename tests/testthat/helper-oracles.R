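# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-implementations (string scans, exhaustive loops) kept
# separate from the package code paths they check.

rc_string <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# naive dictionary-counting tetramer oracle: scan windows, skip any with N,
# pool with reverse complement, normalize
brute_tetramers <- function(s) {
  tbl <- canonical_tetramers()
  counts <- setNames(numeric(136), tbl$classes)
  n <- nchar(s)
  if (n >= 4) {
    for (i in 1:(n - 3)) {
      w <- substr(s, i, i + 3)
      if (grepl("N", w, fixed = TRUE)) next
      r <- rc_string(w)
      counts[min(w, r)] <- counts[min(w, r)] + 1
    }
  }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

random_dna <- function(n, with_n = FALSE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alph, n, replace = TRUE), collapse = "")
}

# brute-force marker counting oracle for bin quality
brute_quality <- function(bin_contigs, hits_list, panel_size = 107) {
  hits <- character(0)
  for (id in bin_contigs) {
    if (!is.null(hits_list[[id]])) hits <- c(hits, hits_list[[id]])
  }
  G <- length(hits)
  N <- length(unique(hits))
  comp <- N / panel_size
  cont <- if (G > 0) (G - N) / G else 0
  f1 <- if (comp > 0) 2 * comp * (1 - cont) / (comp + (1 - cont)) else 0
  list(G = G, N_distinct = N, completeness = comp, contamination = cont,
       f1 = f1)
}

# exhaustive simulation of the greedy multi-run integration: at every step,
# re-evaluate every candidate's quality by brute-force counting and take the
# best F1 below the current contamination level (same tie-break rule:
# larger total length, then smallest contig id)
brute_ensemble <- function(cands, hits_list, lengths, panel_size = 107,
                           ladder = c(0.1, 0.2, 0.3, 0.4, 0.5, 1)) {
  selected <- list()
  for (cont in ladder) {
    repeat {
      best <- NULL; best_q <- NULL
      for (i in seq_along(cands)) {
        if (length(cands[[i]]) == 0L) next
        q <- brute_quality(cands[[i]], hits_list, panel_size)
        if (q$f1 <= 0 || q$contamination >= cont) next
        take <- is.null(best)
        if (!take) {
          if (q$f1 > best_q$f1) take <- TRUE
          else if (q$f1 == best_q$f1) {
            li <- sum(lengths[cands[[i]]]); lb <- sum(lengths[cands[[best]]])
            if (li > lb || (li == lb && min(cands[[i]]) < min(cands[[best]])))
              take <- TRUE
          }
        }
        if (take) { best <- i; best_q <- q }
      }
      if (is.null(best)) break
      selected[[length(selected) + 1L]] <- sort(cands[[best]])
      bin <- cands[[best]]
      cands <- lapply(cands, setdiff, y = bin)
    }
  }
  selected
}

# eps-neighbourhood-graph oracle for density clustering: core points are
# vertices with >= min_pts neighbours (self included); clusters are the
# connected components of the core-core eps graph
brute_core_components <- function(X, eps, min_pts) {
  X <- X / ifelse(sqrt(rowSums(X^2)) > 0, sqrt(rowSums(X^2)), 1)
  D <- as.matrix(dist(X))
  n <- nrow(D)
  core <- vapply(seq_len(n), function(i) sum(D[i, ] <= eps) >= min_pts,
                 logical(1))
  adj <- (D <= eps) & outer(core, core, "&")
  comp <- rep(NA_integer_, n)
  cl <- 0L
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    cl <- cl + 1L
    stack <- i
    while (length(stack) > 0L) {
      v <- stack[[1]]; stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cl
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  comp # NA for non-core points
}

# write a FASTA and return its path
write_test_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), path)
  path
}

# build a sorted+indexed BAM from SAM text lines; returns the BAM path
sam_to_bam <- function(sam_lines) {
  sam <- tempfile(fileext = ".sam")
  writeLines(sam_lines, sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# random marker annotation over a pool of contigs
random_annotation <- function(contig_ids, panel, mean_hits = 3) {
  hits <- lapply(contig_ids, function(id) {
    k <- rpois(1, mean_hits)
    if (k == 0) NULL else sample(panel, k, replace = TRUE)
  })
  names(hits) <- contig_ids
  hits[!vapply(hits, is.null, logical(1))]
}

# small deterministic community + trained model for embedding-level tests
fixture_embedding_task <- function(n_genomes = 3, contigs_per_genome = 25,
                                   n_samples = 5, seed = 42) {
  spec <- community_spec(n_genomes = n_genomes, mode = "short",
                         n_samples = n_samples,
                         contigs_per_genome = contigs_per_genome, seed = seed)
  sim <- simulate_community(spec)
  br <- break_contigs(sim$contigs)
  src <- ifelse(is.na(br$fragments$parent_id), br$fragments$id,
                br$fragments$parent_id)
  raw <- sim$depth[src, , drop = FALSE]
  rownames(raw) <- br$fragments$id
  feats <- feature_matrix(br$fragments,
                          suppressMessages(transform_abundance_matrix(raw)))
  parent_of <- setNames(br$fragments$parent_id, br$fragments$id)
  cannot <- sample_cannot_links(br$fragments$id, parent_of,
                                m = nrow(br$must_links), seed = seed)
  list(sim = sim, fragments = br$fragments, must = br$must_links,
       cannot = cannot, features = feats, parent_of = parent_of)
}
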