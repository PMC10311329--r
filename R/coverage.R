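# Per-contig, per-sample abundance: average mapped read depth per base, then a
# piecewise preprocessing transform whose branch depends on the number of
# samples N and on the sequencing technology:
#
#   f(a) = log(a)                       N < 5, long-read data
#   f(a) = (a / 100) * ceil(a_mean/100) 5 <= N <= 20
#   f(a) = a / sum_i a_i                N > 20
#
# The N < 5 short-read case is not covered by the rule; it is passed through
# unchanged (logged once per run). a_mean and sum_i a_i are computed within the
# sample being transformed (see the methods vignette for the rationale).

#' Average read depth per contig from a BAM file
#'
#' Computes, for each contig, the sum of per-base read depth divided by the
#' contig length (the genome-coverage-histogram average).
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM.
#' @param contig_ids Character vector of contigs to report.
#' @param min_mapq Minimum mapping quality for a read to count (default 0).
#' @return Named numeric vector of mean depths, one per `contig_ids`.
#' @export
depth_from_bam <- function(bam_path, contig_ids, min_mapq = 0L) {
  if (!file.exists(bam_path)) {
    stop("BAM file not found: ", bam_path)
  }
  idx <- c(paste0(bam_path, ".bai"), sub("\\.bam$", ".bai", bam_path))
  if (!any(file.exists(idx))) {
    stop("BAM index (.bai) not found for: ", bam_path,
         "; sort and index the BAM first")
  }
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  missing <- setdiff(contig_ids, names(hdr))
  if (length(missing) > 0L) {
    stop("contig(s) absent from BAM header: ",
         paste(head(missing, 5), collapse = ", "))
  }
  param <- Rsamtools::ScanBamParam(mapqFilter = min_mapq)
  aln <- GenomicAlignments::readGAlignments(bam_path, param = param)
  cov <- GenomicAlignments::coverage(aln)
  out <- vapply(contig_ids, function(id) {
    len <- hdr[[id]]
    if (!id %in% names(cov)) return(0)
    sum(as.numeric(S4Vectors::runValue(cov[[id]])) *
          S4Vectors::runLength(cov[[id]])) / len
  }, numeric(1))
  setNames(out, contig_ids)
}

#' Read a long-format depth table
#'
#' Expects a TSV with header `contig_id  sample_id  depth`, one row per
#' contig/sample pair.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix contigs x samples (rownames contig ids, colnames
#'   sample ids); absent pairs are 0.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop("depth table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "sample_id", "depth")
  if (!all(need %in% names(tab))) {
    stop("depth table must have header columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$depth < 0)) stop("negative depth values in ", path)
  contigs <- unique(tab$contig_id)
  samples <- unique(tab$sample_id)
  m <- matrix(0, length(contigs), length(samples),
              dimnames = list(contigs, samples))
  m[cbind(match(tab$contig_id, contigs), match(tab$sample_id, samples))] <-
    tab$depth
  m
}

#' Preprocess one abundance value
#'
#' Applies the sample-count-dependent piecewise transform to a raw mean depth
#' `a` (see the package vignette). The uncovered case (fewer than 5 samples,
#' short-read data) passes `a` through unchanged.
#'
#' @param a Nonnegative raw abundance value(s).
#' @param n_samples Number of samples N in the binning task.
#' @param long_read Logical; long-read data?
#' @param a_mean Mean abundance over all contigs of this sample (required for
#'   5 <= N <= 20).
#' @param sample_total Sum of abundances over all contigs of this sample
#'   (required for N > 20).
#' @param eps_log Pseudocount added inside the log branch (default 1e-5).
#' @return Transformed value(s), same length as `a`.
#' @export
transform_abundance <- function(a, n_samples, long_read = FALSE,
                                a_mean = NULL, sample_total = NULL,
                                eps_log = 1e-5) {
  stopifnot(all(a >= 0), n_samples >= 1)
  if (n_samples < 5) {
    if (long_read) {
      return(log(a + eps_log))
    }
    return(a) # uncovered branch: identity pass-through
  }
  if (n_samples <= 20) {
    if (is.null(a_mean)) {
      stop("a_mean is required when 5 <= n_samples <= 20")
    }
    return((a / 100) * ceiling(a_mean / 100))
  }
  if (is.null(sample_total) || sample_total == 0) {
    stop("a positive sample_total is required when n_samples > 20")
  }
  a / sample_total
}

#' Preprocess a full abundance matrix
#'
#' Applies [transform_abundance()] column-wise (per sample), computing each
#' sample's `a_mean` and total over the contigs of the matrix.
#'
#' @param raw Numeric matrix contigs x samples of raw mean depths.
#' @param long_read Logical; long-read data?
#' @param eps_log Pseudocount for the log branch.
#' @return Matrix of identical shape with transformed values.
#' @export
transform_abundance_matrix <- function(raw, long_read = FALSE, eps_log = 1e-5) {
  raw <- as.matrix(raw)
  n <- ncol(raw)
  if (n < 5 && !long_read) {
    message("abundance transform: N = ", n,
            " short-read samples; passing raw depths through unchanged")
  }
  out <- raw
  for (j in seq_len(n)) {
    out[, j] <- transform_abundance(
      raw[, j], n_samples = n, long_read = long_read,
      a_mean = mean(raw[, j]), sample_total = sum(raw[, j]),
      eps_log = eps_log
    )
  }
  out
}
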