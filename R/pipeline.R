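# End-to-end orchestration: features -> constraints -> contrastive training
# -> embedding of the original (unbroken) contigs -> mode-dependent
# clustering -> bin-size filtering -> standard-format outputs.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default.
#'
#' @param min_length Minimum input contig length (bp).
#' @param break_min_length Minimum contig length for must-link break-up (bp).
#' @param hidden Hidden-layer widths of the embedding network.
#' @param dropout Dropout rate.
#' @param epochs,batch_size,learning_rate,margin Training parameters.
#' @param max_edges Graph neighbour cap (short-read mode).
#' @param eps_list DBSCAN epsilon ladder (long-read mode).
#' @param min_samples DBSCAN core-point neighbourhood size.
#' @param cont_ladder Contamination ladder for ensemble integration.
#' @param emit_leftover Promote large unselected contigs to singleton bins
#'   (long-read mode).
#' @param min_bin_size Minimum emitted bin size (bp, default 200 kb).
#' @param cannot_link_scope `"within_sample"` or `"global"` sampling of
#'   cannot-links in multi-sample mode.
#' @param seed Master seed for the whole run.
#' @return A `binning_config` list.
#' @export
binning_config <- function(min_length = 1000L, break_min_length = 4000L,
                           hidden = c(512L, 512L), dropout = 0.2,
                           epochs = 30L, batch_size = 256L,
                           learning_rate = 1e-3, margin = 1,
                           max_edges = 200L,
                           eps_list = DEFAULT_EPS_LADDER, min_samples = 5L,
                           cont_ladder = DEFAULT_CONT_LADDER,
                           emit_leftover = FALSE, min_bin_size = 200000,
                           cannot_link_scope = c("within_sample", "global"),
                           seed = 0L) {
  structure(
    list(min_length = min_length, break_min_length = break_min_length,
         hidden = hidden, dropout = dropout, epochs = epochs,
         batch_size = batch_size, learning_rate = learning_rate,
         margin = margin, max_edges = max_edges, eps_list = eps_list,
         min_samples = min_samples, cont_ladder = cont_ladder,
         emit_leftover = emit_leftover, min_bin_size = min_bin_size,
         cannot_link_scope = match.arg(cannot_link_scope),
         seed = as.integer(seed)),
    class = "binning_config"
  )
}

# Resolve a depth argument (matrix, depth-TSV path, or vector of BAM paths)
# into a contigs x samples raw depth matrix covering `contig_ids`.
resolve_depth <- function(depth, contig_ids) {
  if (is.matrix(depth) || is.data.frame(depth)) {
    m <- as.matrix(depth)
  } else if (is.character(depth)) {
    if (all(grepl("\\.bam$", depth, ignore.case = TRUE))) {
      cols <- lapply(depth, depth_from_bam, contig_ids = contig_ids)
      m <- do.call(cbind, cols)
      colnames(m) <- if (!is.null(names(depth))) names(depth) else
        paste0("s", seq_along(depth))
    } else {
      stopifnot(length(depth) == 1L)
      m <- read_depth_table(depth)
    }
  } else {
    stop("depth must be a matrix, a depth-TSV path, or BAM path(s)")
  }
  missing <- setdiff(contig_ids, rownames(m))
  if (length(missing) > 0L) {
    stop("no depth for contig(s): ", paste(head(missing, 5), collapse = ", "))
  }
  m[contig_ids, , drop = FALSE]
}

# Shared core: contigs + raw depth -> trained model + embeddings of the
# original contigs. Fragments created by break-up inherit the parent's raw
# abundance row.
embed_contig_set <- function(contigs, raw_depth, long_read, config,
                             cannot_groups = NULL) {
  br <- break_contigs(contigs, config$break_min_length)
  frags <- br$fragments
  src <- ifelse(is.na(frags$parent_id), frags$id, frags$parent_id)
  raw_frag <- raw_depth[src, , drop = FALSE]
  rownames(raw_frag) <- frags$id
  trans_frag <- transform_abundance_matrix(raw_frag, long_read)
  feats_train <- feature_matrix(frags, trans_frag)
  parent_of <- setNames(frags$parent_id, frags$id)
  if (is.null(cannot_groups)) {
    cannot <- sample_cannot_links(frags$id, parent_of,
                                  m = nrow(br$must_links), seed = config$seed)
  } else {
    # multi-sample, within-sample scope: sample separately per group
    groups <- split(frags$id, cannot_groups[frags$id])
    parts <- lapply(seq_along(groups), function(i) {
      gids <- groups[[i]]
      m_g <- sum(!is.na(parent_of[gids])) / 2
      sample_cannot_links(gids, parent_of, m = floor(m_g),
                          seed = config$seed + i)
    })
    cannot <- do.call(rbind, parts)
    if (nrow(cannot) > nrow(br$must_links)) {
      cannot <- cannot[seq_len(nrow(br$must_links)), , drop = FALSE]
    }
  }
  cs <- constraint_set(br$must_links, cannot)
  model <- new_siamese_model(ncol(feats_train), hidden = config$hidden,
                             dropout = config$dropout, seed = config$seed)
  tr <- train_siamese(model, feats_train, cs,
                      training_config(epochs = config$epochs,
                                      batch_size = config$batch_size,
                                      learning_rate = config$learning_rate,
                                      margin = config$margin,
                                      seed = config$seed))
  trans_orig <- transform_abundance_matrix(raw_depth, long_read)
  feats_orig <- feature_matrix(contigs, trans_orig)
  list(model = tr$model, loss_trace = tr$loss_trace,
       embeddings = model_forward(tr$model, feats_orig),
       abundances = trans_orig, constraints = cs)
}

# Assemble a binning_result from an assignment vector, applying the output
# size filter.
finalize_result <- function(assignments, contigs, annotation, mode, config) {
  lengths <- setNames(contigs$length, contigs$id)
  bins <- split(names(assignments), assignments)
  total <- vapply(bins, function(b) sum(lengths[b]), numeric(1))
  bins <- bins[total >= config$min_bin_size]
  bin_ids <- sprintf("bin_%04d", seq_along(bins))
  names(bins) <- bin_ids
  assignments <- setNames(rep(bin_ids, lengths(bins)),
                          unlist(bins, use.names = FALSE))
  summaries <- do.call(rbind, lapply(bin_ids, function(b) {
    ctgs <- bins[[b]]
    q <- if (!is.null(annotation)) score_bin(ctgs, annotation) else
      list(completeness = NA_real_, contamination = NA_real_, f1 = NA_real_)
    data.frame(bin_id = b, n_contigs = length(ctgs),
               total_length = sum(lengths[ctgs]),
               completeness = q$completeness,
               contamination = q$contamination, f1 = q$f1,
               stringsAsFactors = FALSE)
  }))
  if (is.null(summaries)) {
    summaries <- data.frame(bin_id = character(0), n_contigs = integer(0),
                            total_length = numeric(0),
                            completeness = numeric(0),
                            contamination = numeric(0), f1 = numeric(0))
  }
  structure(
    list(assignments = assignments, bins = bins, summary = summaries,
         unbinned = setdiff(contigs$id, names(assignments)),
         mode = mode, config = config,
         version = as.character(utils::packageVersion("contrabin"))),
    class = "binning_result"
  )
}

#' @export
print.binning_result <- function(x, ...) {
  cat("binning result (", x$mode, " mode): ", length(x$bins), " bins, ",
      length(x$assignments), " contigs binned, ", length(x$unbinned),
      " unbinned\n", sep = "")
  invisible(x)
}

#' Bin one assembly
#'
#' Runs the full pipeline on a single assembly: read contigs, compute and
#' preprocess abundances, generate self-supervised constraints, train the
#' contrastive embedding, embed the original contigs, cluster by mode and
#' filter bins by `min_bin_size`. Fully deterministic given `config$seed`.
#'
#' @param fasta Path to the assembly FASTA.
#' @param depth Raw abundance source: contigs x samples matrix, depth-TSV
#'   path, or vector of sorted+indexed BAM paths (one per sample).
#' @param mode `"short"` or `"long"` read assembly.
#' @param marker_tsv Optional marker annotation TSV (`contig_id`,
#'   `marker_id`); required in long mode, enables reclustering in short
#'   mode.
#' @param config A [binning_config()].
#' @return A `binning_result`: `assignments` (contig -> bin), `bins`,
#'   `summary` (per-bin table), `unbinned`, `mode`, `config`, plus the
#'   trained `model` and `loss_trace`.
#' @export
run_single_sample <- function(fasta, depth, mode = c("short", "long"),
                              marker_tsv = NULL, config = binning_config()) {
  mode <- match.arg(mode)
  contigs <- read_contigs(fasta, config$min_length)
  if (nrow(contigs) == 0L) stop("no contigs pass the length filter")
  raw <- resolve_depth(depth, contigs$id)
  annotation <- if (!is.null(marker_tsv)) {
    annotate_markers(contigs, "precomputed-tsv", tsv_path = marker_tsv)
  }
  if (mode == "long" && is.null(annotation)) {
    stop("long-read mode requires a marker annotation (marker_tsv)")
  }
  emb <- embed_contig_set(contigs, raw, long_read = (mode == "long"), config)
  lengths <- setNames(contigs$length, contigs$id)
  assignments <- if (mode == "short") {
    cluster_short(emb$embeddings, emb$abundances, annotation, lengths,
                  max_edges = config$max_edges, seed = config$seed)
  } else {
    cluster_long(emb$embeddings, annotation, lengths,
                 eps_list = config$eps_list,
                 min_samples = config$min_samples,
                 cont_ladder = config$cont_ladder,
                 emit_leftover = config$emit_leftover,
                 min_bin_size = config$min_bin_size)
  }
  res <- finalize_result(assignments, contigs, annotation, mode, config)
  res$model <- emb$model
  res$loss_trace <- emb$loss_trace
  res
}

#' Bin several samples jointly (multi-sample mode)
#'
#' Contigs of all samples are pooled under sample-tagged ids
#' (`<sample>:<contig>`), one embedding model is trained on the pooled
#' constraint set with the full cross-sample abundance vector (N = number of
#' samples), and clustering runs within each sample's contig set.
#'
#' @param fastas Named character vector of per-sample FASTA paths.
#' @param depths Named list (same names) of per-sample raw depth sources;
#'   each must cover that sample's contigs in every sample (columns =
#'   samples).
#' @param mode `"short"` or `"long"`.
#' @param marker_tsvs Optional named list of per-sample marker TSVs.
#' @param config A [binning_config()].
#' @return Named list of per-sample `binning_result`s (contig ids keep the
#'   sample tag).
#' @export
run_multi_sample <- function(fastas, depths, mode = c("short", "long"),
                             marker_tsvs = NULL, config = binning_config()) {
  mode <- match.arg(mode)
  samples <- names(fastas)
  if (is.null(samples) || any(!nzchar(samples))) {
    stop("fastas must be a named vector of per-sample paths")
  }
  tag <- function(sample, ids) {
    if (any(grepl(":", ids, fixed = TRUE))) {
      stop("contig ids must not contain ':' (reserved for sample tagging)")
    }
    paste0(sample, ":", ids)
  }
  per <- lapply(samples, function(s) {
    ctg <- read_contigs(fastas[[s]], config$min_length)
    raw <- resolve_depth(depths[[s]], ctg$id)
    ctg$id <- tag(s, ctg$id)
    rownames(raw) <- ctg$id
    list(contigs = ctg, raw = raw)
  })
  names(per) <- samples
  contigs <- do.call(rbind, lapply(per, `[[`, "contigs"))
  if (anyDuplicated(contigs$id)) {
    stop("contig id collision after sample tagging")
  }
  raw <- do.call(rbind, lapply(per, `[[`, "raw"))
  raw <- raw[contigs$id, , drop = FALSE]
  sample_of <- setNames(rep(samples, vapply(per, function(p) nrow(p$contigs),
                                            integer(1))), contigs$id)
  annotation <- NULL
  if (!is.null(marker_tsvs)) {
    hits <- list()
    for (s in names(marker_tsvs)) {
      a <- read_marker_annotation(marker_tsvs[[s]])
      names(a$hits) <- tag(s, names(a$hits))
      hits <- c(hits, a$hits)
    }
    annotation <- marker_annotation(hits)
  }
  if (mode == "long" && is.null(annotation)) {
    stop("long-read mode requires marker annotations (marker_tsvs)")
  }
  # fragment ids keep the "<sample>:" prefix of their parent, so the sample
  # label of any (fragment or original) id is its tag prefix
  cannot_groups <- if (config$cannot_link_scope == "within_sample") {
    all_ids <- c(contigs$id, paste0(contigs$id, "_1"), paste0(contigs$id, "_2"))
    setNames(sub(":.*$", "", all_ids), all_ids)
  }
  emb <- embed_contig_set(contigs, raw, long_read = (mode == "long"), config,
                          cannot_groups = cannot_groups)
  lengths <- setNames(contigs$length, contigs$id)
  out <- lapply(samples, function(s) {
    sel <- contigs$id[sample_of[contigs$id] == s]
    emb_s <- emb$embeddings[sel, , drop = FALSE]
    ab_s <- emb$abundances[sel, , drop = FALSE]
    assignments <- if (mode == "short") {
      cluster_short(emb_s, ab_s, annotation, lengths,
                    max_edges = config$max_edges, seed = config$seed)
    } else {
      cluster_long(emb_s, annotation, lengths,
                   eps_list = config$eps_list,
                   min_samples = config$min_samples,
                   cont_ladder = config$cont_ladder,
                   emit_leftover = config$emit_leftover,
                   min_bin_size = config$min_bin_size)
    }
    res <- finalize_result(assignments,
                           contigs[contigs$id %in% sel, , drop = FALSE],
                           annotation, mode, config)
    res$sample <- s
    res
  })
  names(out) <- samples
  out
}

#' Write binning outputs
#'
#' Writes one FASTA per bin, a membership TSV (`contig_id`, `bin_id`), a
#' per-bin summary TSV and a run manifest into `out_dir`.
#'
#' @param result A `binning_result`.
#' @param contigs Contig table holding the sequences (ids must cover the
#'   binned contigs).
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the output directory.
#' @export
write_bins <- function(result, contigs, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force) {
    stop("output directory ", out_dir,
         " exists and is not empty (use force = TRUE to overwrite)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- setNames(contigs$sequence, contigs$id)
  for (b in names(result$bins)) {
    ctgs <- sort(result$bins[[b]])
    dss <- Biostrings::DNAStringSet(seqs[ctgs])
    Biostrings::writeXStringSet(dss, file.path(out_dir, paste0(b, ".fasta")))
  }
  memb <- data.frame(contig_id = names(result$assignments),
                     bin_id = unname(result$assignments))
  memb <- memb[order(memb$contig_id), ]
  write.table(memb, file.path(out_dir, "membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$summary, file.path(out_dir, "bins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- result$config
  manifest <- c(
    paste0("tool_version=", result$version),
    paste0("mode=", result$mode),
    paste0("n_bins=", length(result$bins)),
    vapply(names(cfg), function(k) {
      paste0(k, "=", paste(format(cfg[[k]], trim = TRUE), collapse = ","))
    }, "")
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
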