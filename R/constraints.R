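# Self-supervised constraint generation. Must-links come from simulated
# break-up of long contigs (the two halves of one contig must co-bin);
# cannot-links from random contig pairs, which are almost always from
# different genomes in a diverse community. The number of cannot-links is
# capped at min(m, 4e6), m = number of must-links, to control training time
# and the must/cannot ratio.

CANNOT_LINK_CAP <- 4000000L

#' Break long contigs into must-linked halves
#'
#' Every contig at least `break_min_length` bp long is split at its midpoint
#' into two fragments that inherit the parent's identity via `parent_id`;
#' each split contributes one must-link pair. Shorter contigs pass through
#' unchanged. Fragments are used for embedding training only; clustering
#' operates on the original contigs.
#'
#' @param contigs Contig table from [read_contigs()].
#' @param break_min_length Minimum length for a contig to be split
#'   (default 4000 bp).
#' @return List with `fragments` (contig table where split contigs are
#'   replaced by their two halves) and `must_links` (data frame `a`, `b` of
#'   fragment id pairs).
#' @export
break_contigs <- function(contigs, break_min_length = 4000L) {
  split <- contigs$length >= break_min_length
  keep <- contigs[!split, , drop = FALSE]
  long <- contigs[split, , drop = FALSE]
  if (nrow(long) == 0L) {
    return(list(fragments = contigs,
                must_links = data.frame(a = character(0), b = character(0),
                                        stringsAsFactors = FALSE)))
  }
  half <- long$length %/% 2L
  f1 <- data.frame(
    id = paste0(long$id, "_1"),
    sequence = substr(long$sequence, 1L, half),
    length = half,
    parent_id = long$id,
    stringsAsFactors = FALSE
  )
  f2 <- data.frame(
    id = paste0(long$id, "_2"),
    sequence = substr(long$sequence, half + 1L, long$length),
    length = long$length - half,
    parent_id = long$id,
    stringsAsFactors = FALSE
  )
  frags <- rbind(keep, f1, f2)
  if (anyDuplicated(frags$id)) {
    stop("fragment id collision after break-up; contig ids ending in _1/_2 ",
         "clash with generated fragment names")
  }
  list(fragments = frags,
       must_links = data.frame(a = f1$id, b = f2$id, stringsAsFactors = FALSE))
}

#' Sample cannot-link pairs
#'
#' Draws up to `min(m, 4e6)` distinct unordered pairs uniformly at random
#' among contigs that do not share a `parent_id` (sibling fragments are known
#' must-links and are never labelled cannot-link). Deterministic given
#' `seed`.
#'
#' @param contig_ids Character vector of candidate ids.
#' @param parent_of Named character vector mapping id -> parent id (NA when
#'   the contig is not a fragment).
#' @param m Number of must-link constraints (the cap reference).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `a`, `b` (a < b lexicographically).
#' @export
sample_cannot_links <- function(contig_ids, parent_of, m, seed = 0L) {
  n <- length(contig_ids)
  target <- min(m, CANNOT_LINK_CAP)
  empty <- data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2L || target < 1L) {
    return(empty)
  }
  par <- parent_of[contig_ids]
  lineage <- ifelse(is.na(par), contig_ids, unname(par))
  if (length(unique(lineage)) < 2L) {
    warning("fewer than 2 distinct parent lineages; no cannot-links sampled")
    return(empty)
  }
  is_valid <- function(i, j) lineage[i] != lineage[j]
  n_pairs <- choose(n, 2)
  with_seed(seed, {
    if (n_pairs <= 4L * target) {
      # small problem: enumerate all valid pairs, then sample
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      ok <- is_valid(idx[, 1], idx[, 2])
      idx <- idx[ok, , drop = FALSE]
      avail <- nrow(idx)
      if (avail < target) {
        warning("only ", avail, " distinct cannot-link pairs available; ",
                target, " requested")
      }
      pick <- idx[sample.int(avail, min(avail, target)), , drop = FALSE]
      i <- pick[, 1]; j <- pick[, 2]
    } else {
      # rejection-sample unordered pairs without replacement
      seen <- new.env(hash = TRUE, parent = emptyenv())
      i <- integer(target); j <- integer(target)
      got <- 0L
      while (got < target) {
        draw <- max(64L, 2L * (target - got))
        ii <- sample.int(n, draw, replace = TRUE)
        jj <- sample.int(n, draw, replace = TRUE)
        for (k in seq_len(draw)) {
          if (got >= target) break
          a <- min(ii[k], jj[k]); b <- max(ii[k], jj[k])
          if (a == b || !is_valid(a, b)) next
          key <- paste0(a, "_", b)
          if (!is.null(seen[[key]])) next
          assign(key, TRUE, envir = seen)
          got <- got + 1L
          i[got] <- a; j[got] <- b
        }
      }
    }
    a <- contig_ids[i]; b <- contig_ids[j]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    data.frame(a = a, b = b, stringsAsFactors = FALSE)
  })
}

#' Assemble and validate a constraint set
#'
#' @param must_links,cannot_links Data frames with columns `a`, `b`.
#' @return Object of class `constraint_set` with elements `must_links`,
#'   `cannot_links`, `m`.
#' @export
constraint_set <- function(must_links, cannot_links) {
  key <- function(d) paste(pmin(d$a, d$b), pmax(d$a, d$b), sep = "\r")
  if (any(must_links$a == must_links$b) || any(cannot_links$a == cannot_links$b)) {
    stop("constraint pairs (x, x) are not allowed")
  }
  both <- intersect(key(must_links), key(cannot_links))
  if (length(both) > 0L) {
    stop("pair(s) appear in both must-link and cannot-link sets")
  }
  if (nrow(cannot_links) > min(nrow(must_links), CANNOT_LINK_CAP)) {
    stop("cannot-link count exceeds min(m, 4e6) cap")
  }
  structure(
    list(must_links = must_links, cannot_links = cannot_links,
         m = nrow(must_links)),
    class = "constraint_set"
  )
}

#' Dump constraints as an audit TSV
#'
#' @param constraints A `constraint_set`.
#' @param path Output TSV path (columns pair_id, contig_a, contig_b, label).
#' @export
write_constraints_tsv <- function(constraints, path) {
  m <- constraints$must_links
  c0 <- constraints$cannot_links
  tab <- data.frame(
    pair_id = seq_len(nrow(m) + nrow(c0)),
    contig_a = c(m$a, c0$a),
    contig_b = c(m$b, c0$b),
    label = c(rep(1L, nrow(m)), rep(0L, nrow(c0)))
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
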