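# Ground-truth community simulator. Genomes get distinct compositional
# signatures via per-genome 3rd-order Markov transition matrices (Dirichlet
# perturbations of the uniform chain, spread controlled by `divergence`);
# contig length models mimic short-read-like (many lognormal-length contigs)
# or long-read-like (few long contigs, including single-contig genomes)
# assemblies; per-sample genome abundances are lognormal and per-contig
# depths get Poisson counting jitter; one copy of each of the 107 marker ids
# is planted per genome, uniformly over its contigs. Ground-truth
# contig -> genome labels are retained so every pipeline stage is testable.

#' Specify a synthetic community
#'
#' @param n_genomes Number of genomes.
#' @param mode `"short"` (short-read-like contigs) or `"long"`.
#' @param n_samples Number of samples with independent abundance profiles.
#' @param divergence Compositional divergence knob: per-context transition
#'   probabilities are Dirichlet(1/divergence); 0 gives the uniform chain
#'   for every genome (genomes compositionally indistinguishable).
#' @param contigs_per_genome Contigs per genome (short mode).
#' @param contig_meanlog,contig_sdlog Lognormal contig-length parameters in
#'   log-bp (short mode).
#' @param genome_length Genome length in bp (long mode).
#' @param max_contigs_long Upper bound on contigs per genome (long mode);
#'   the first genome is always a single contig.
#' @param abund_meanlog,abund_sdlog Lognormal per-sample genome abundance
#'   parameters (log mean depth).
#' @param min_contig Minimum simulated contig length (bp).
#' @param seed RNG seed; all outputs are deterministic given the spec.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_genomes = 20L, mode = c("short", "long"),
                           n_samples = 5L, divergence = 0.1,
                           contigs_per_genome = 60L,
                           contig_meanlog = 8.5, contig_sdlog = 0.7,
                           genome_length = 500000L, max_contigs_long = 10L,
                           abund_meanlog = 3, abund_sdlog = 1,
                           min_contig = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_genomes >= 1, n_samples >= 1, divergence >= 0)
  if (mode == "long" && genome_length < max_contigs_long * min_contig) {
    stop("infeasible spec: genome_length too small for the contig model")
  }
  structure(
    list(n_genomes = n_genomes, mode = mode, n_samples = n_samples,
         divergence = divergence, contigs_per_genome = contigs_per_genome,
         contig_meanlog = contig_meanlog, contig_sdlog = contig_sdlog,
         genome_length = genome_length, max_contigs_long = max_contigs_long,
         abund_meanlog = abund_meanlog, abund_sdlog = abund_sdlog,
         min_contig = min_contig, seed = seed),
    class = "community_spec"
  )
}

# Dirichlet(1/divergence) rows over the 4 bases for each of the 64 contexts;
# divergence 0 = uniform chain.
random_transition_matrix <- function(divergence) {
  if (divergence <= 0) {
    return(matrix(0.25, 64, 4))
  }
  g <- matrix(rgamma(64 * 4, shape = 1 / divergence), 64, 4)
  g / rowSums(g)
}

#' Simulate a ground-truth community
#'
#' @param spec A [community_spec()].
#' @param out_dir Optional directory; when given, writes `contigs.fasta`,
#'   `depth.tsv` (long format), `markers.tsv` and `truth.tsv` there,
#'   byte-identically for a fixed spec.
#' @return List with `contigs` (contig table), `depth` (matrix contigs x
#'   samples of raw mean depths), `markers` (data frame contig_id,
#'   marker_id), `truth` (data frame contig_id, genome_id), `abundance`
#'   (matrix genomes x samples) and `spec`.
#' @export
simulate_community <- function(spec, out_dir = NULL) {
  panel <- default_marker_panel()
  sim <- with_seed(spec$seed, {
    ids <- character(0); seqs <- character(0); genome_of <- character(0)
    markers <- list()
    for (g in seq_len(spec$n_genomes)) {
      gid <- sprintf("g%02d", g)
      trans <- random_transition_matrix(spec$divergence)
      if (spec$mode == "short") {
        lens <- pmax(spec$min_contig,
                     round(rlnorm(spec$contigs_per_genome,
                                  spec$contig_meanlog, spec$contig_sdlog)))
      } else {
        n_ctg <- if (g == 1L) 1L else sample(2:spec$max_contigs_long, 1L)
        w <- rgamma(n_ctg, shape = 5)
        lens <- round(spec$genome_length * w / sum(w))
        lens <- pmax(lens, spec$min_contig)
        lens[n_ctg] <- lens[n_ctg] + (spec$genome_length - sum(lens))
        if (lens[n_ctg] < spec$min_contig) {
          stop("infeasible spec: residual contig below min_contig")
        }
      }
      cids <- sprintf("%s_c%03d", gid, seq_along(lens))
      cseqs <- vapply(lens, simulate_markov_sequence, "", trans = trans)
      ids <- c(ids, cids); seqs <- c(seqs, cseqs)
      genome_of <- c(genome_of, rep(gid, length(cids)))
      markers[[gid]] <- data.frame(
        contig_id = cids[sample.int(length(cids), length(panel),
                                    replace = TRUE)],
        marker_id = panel,
        stringsAsFactors = FALSE
      )
    }
    contigs <- data.frame(id = ids, sequence = seqs, length = nchar(seqs),
                          parent_id = NA_character_, stringsAsFactors = FALSE)
    genomes <- sprintf("g%02d", seq_len(spec$n_genomes))
    abundance <- matrix(
      rlnorm(spec$n_genomes * spec$n_samples,
             spec$abund_meanlog, spec$abund_sdlog),
      spec$n_genomes, spec$n_samples,
      dimnames = list(genomes, sprintf("s%02d", seq_len(spec$n_samples)))
    )
    depth <- matrix(0, nrow(contigs), spec$n_samples,
                    dimnames = list(contigs$id, colnames(abundance)))
    for (i in seq_len(nrow(contigs))) {
      lam <- abundance[genome_of[i], ] * contigs$length[i]
      depth[i, ] <- rpois(spec$n_samples, lam) / contigs$length[i]
    }
    markers <- do.call(rbind, markers)
    markers <- markers[order(markers$contig_id, markers$marker_id), ]
    rownames(markers) <- NULL
    list(contigs = contigs, depth = depth, markers = markers,
         truth = data.frame(contig_id = contigs$id, genome_id = genome_of,
                            stringsAsFactors = FALSE),
         abundance = abundance)
  })
  sim$spec <- spec
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    dss <- Biostrings::DNAStringSet(setNames(sim$contigs$sequence,
                                             sim$contigs$id))
    Biostrings::writeXStringSet(dss, file.path(out_dir, "contigs.fasta"))
    long <- data.frame(
      contig_id = rep(rownames(sim$depth), ncol(sim$depth)),
      sample_id = rep(colnames(sim$depth), each = nrow(sim$depth)),
      depth = as.vector(sim$depth)
    )
    write.table(long, file.path(out_dir, "depth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$markers, file.path(out_dir, "markers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  sim
}

#' Evaluate bins against ground truth
#'
#' Per bin, the majority genome is the genome contributing the most base
#' pairs; completeness is the fraction of that genome's total bp captured by
#' the bin and contamination the fraction of the bin's bp not from the
#' majority genome. A genome counts as recovered when some bin passes both
#' thresholds with it as majority genome.
#'
#' @param assignments Named character vector contig id -> bin id (e.g.
#'   `result$assignments`), or a `binning_result`.
#' @param truth Data frame `contig_id`, `genome_id` covering every binned
#'   contig.
#' @param contig_lengths Named numeric vector of contig lengths for all
#'   contigs in `truth`.
#' @param comp_threshold,cont_threshold High-quality thresholds (defaults
#'   0.9 and 0.05).
#' @return List with `per_bin` (data frame), `n_hq`,
#'   `recovered_genomes` (character), `recovery_fraction`, and `strata`
#'   (counts at completeness 0.9/0.8/0.7 x contamination 0.05/0.1).
#' @export
evaluate_bins <- function(assignments, truth, contig_lengths,
                          comp_threshold = 0.9, cont_threshold = 0.05) {
  if (inherits(assignments, "binning_result")) {
    assignments <- assignments$assignments
  }
  binned <- names(assignments)
  missing <- setdiff(binned, truth$contig_id)
  if (length(missing) > 0L) {
    stop("binned contig(s) missing from truth: ",
         paste(head(missing, 5), collapse = ", "))
  }
  genome_of <- setNames(truth$genome_id, truth$contig_id)
  genome_bp <- tapply(contig_lengths[truth$contig_id], truth$genome_id, sum)
  per_bin <- do.call(rbind, lapply(split(binned, assignments[binned]),
                                   function(ctgs) {
    bp <- tapply(contig_lengths[ctgs], genome_of[ctgs], sum)
    maj <- names(bp)[which.max(bp)]
    data.frame(
      genome = maj,
      completeness = unname(bp[maj] / genome_bp[maj]),
      contamination = unname(1 - bp[maj] / sum(bp)),
      total_length = unname(sum(bp)),
      n_contigs = length(ctgs),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(per_bin)) {
    per_bin <- data.frame(genome = character(0), completeness = numeric(0),
                          contamination = numeric(0), total_length = numeric(0),
                          n_contigs = integer(0))
  } else {
    per_bin <- cbind(bin_id = rownames(per_bin), per_bin)
    rownames(per_bin) <- NULL
  }
  hq <- per_bin$completeness > comp_threshold &
    per_bin$contamination < cont_threshold
  recovered <- unique(per_bin$genome[hq])
  strata <- expand.grid(comp = c(0.9, 0.8, 0.7), cont = c(0.05, 0.1))
  strata$n_bins <- mapply(function(cp, ct) {
    sum(per_bin$completeness > cp & per_bin$contamination < ct)
  }, strata$comp, strata$cont)
  list(per_bin = per_bin, n_hq = sum(hq), recovered_genomes = recovered,
       recovery_fraction = length(recovered) / length(genome_bp),
       strata = strata)
}
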