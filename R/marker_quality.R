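# Single-copy marker-gene (SCG) accounting. A bacterial genome carries one
# copy of each of a panel of 107 marker genes, so within one bin:
#   G = total marker hits, N = distinct markers,
#   completeness  = N / 107
#   contamination = (G - N) / G          (0 when G = 0)
#   F1 = 2 * comp * (1 - cont) / (comp + (1 - cont))
# The scoring layer treats marker ids as opaque strings; the shipped default
# panel is a synthetic set of 107 symbolic ids (SCG001..SCG107) matching the
# simulator. For real data supply the panel and annotation produced by an
# external gene caller + profile search.

MARKER_PANEL_SIZE <- 107L

#' The default single-copy marker panel
#'
#' @return Character vector of 107 symbolic marker ids.
#' @export
default_marker_panel <- function() {
  path <- system.file("extdata", "marker_panel.txt", package = "contrabin")
  readLines(path)
}

#' Read a precomputed marker annotation TSV
#'
#' Expects a TSV with header `contig_id  marker_id`; each row is one hit, so
#' duplicated rows mean multiple hits of that marker on that contig.
#'
#' @param path Path to the TSV.
#' @param panel Character vector of allowed marker ids.
#' @return Object of class `marker_annotation`: a list with `hits` (named
#'   list contig_id -> character vector of marker hits) and `panel`.
#' @export
read_marker_annotation <- function(path, panel = default_marker_panel()) {
  if (!file.exists(path)) stop("marker annotation not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("marker TSV is empty (header required)")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("contig_id", "marker_id"))) {
    stop("marker TSV line 1: expected header 'contig_id\tmarker_id'")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    stop("marker TSV line ", bad[1] + 1L, ": expected 2 tab-separated fields")
  }
  contig <- vapply(parts, `[[`, "", 1L)
  marker <- vapply(parts, `[[`, "", 2L)
  outside <- setdiff(unique(marker), panel)
  if (length(outside) > 0L) {
    stop("marker id(s) outside the declared panel: ",
         paste(head(outside, 5), collapse = ", "))
  }
  marker_annotation(split(marker, contig), panel)
}

#' Construct a marker annotation from a hits list
#'
#' @param hits Named list mapping contig id to a character vector (multiset)
#'   of marker hits.
#' @param panel Allowed marker ids.
#' @return A `marker_annotation`.
#' @export
marker_annotation <- function(hits = list(), panel = default_marker_panel()) {
  outside <- setdiff(unique(unlist(hits, use.names = FALSE)), panel)
  if (length(outside) > 0L) {
    stop("marker id(s) outside the declared panel: ",
         paste(head(outside, 5), collapse = ", "))
  }
  structure(list(hits = hits, panel = panel), class = "marker_annotation")
}

#' Annotate contigs with marker-gene hits
#'
#' `precomputed-tsv` mode reads an existing annotation table. `external-scan`
#' mode (gene calling plus profile HMM search over the contig sequences) is a
#' plugin point and requires external tools; it is not bundled.
#'
#' @param contigs Contig table (used to validate ids in tsv mode).
#' @param mode `"precomputed-tsv"` or `"external-scan"`.
#' @param tsv_path Annotation TSV (tsv mode).
#' @param panel Allowed marker ids.
#' @return A `marker_annotation`.
#' @export
annotate_markers <- function(contigs, mode = c("precomputed-tsv", "external-scan"),
                             tsv_path = NULL, panel = default_marker_panel()) {
  mode <- match.arg(mode)
  if (mode == "external-scan") {
    stop("external-scan mode needs a gene caller (e.g. prodigal) and a ",
         "profile HMM search (e.g. hmmsearch) configured with a profile ",
         "database; supply a precomputed annotation TSV instead")
  }
  if (is.null(tsv_path)) stop("tsv_path is required in precomputed-tsv mode")
  ann <- read_marker_annotation(tsv_path, panel)
  stray <- setdiff(names(ann$hits), contigs$id)
  if (length(stray) > 0L) {
    warning(length(stray), " annotated contig(s) not in the contig set ",
            "(dropped): ", paste(head(stray, 3), collapse = ", "))
    ann$hits <- ann$hits[setdiff(names(ann$hits), stray)]
  }
  ann
}

#' Score a bin from its marker content
#'
#' @param bin_contigs Character vector of contig ids in the bin.
#' @param annotation A `marker_annotation`.
#' @return List of class `quality_score`: `G`, `N_distinct`, `completeness`,
#'   `contamination`, `f1`.
#' @export
score_bin <- function(bin_contigs, annotation) {
  hits <- unlist(annotation$hits[intersect(bin_contigs, names(annotation$hits))],
                 use.names = FALSE)
  G <- length(hits)
  N <- length(unique(hits))
  comp <- N / length(annotation$panel)
  cont <- if (G > 0) (G - N) / G else 0
  denom <- comp + (1 - cont)
  f1 <- if (denom > 0 && comp > 0) 2 * comp * (1 - cont) / denom else 0
  structure(list(G = G, N_distinct = N, completeness = comp,
                 contamination = cont, f1 = f1),
            class = "quality_score")
}
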