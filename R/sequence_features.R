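# Compositional features: canonical (reverse-complement-collapsed) tetramer
# frequencies. 256 tetramers collapse to 136 classes: 16 palindromes plus 120
# complementary pairs, each represented by its lexicographically smaller member.

.tetramer_cache <- new.env(parent = emptyenv())

#' Canonical tetramer classes
#'
#' Enumerates the 136 equivalence classes of DNA 4-mers under reverse
#' complementation. Each class is named by its lexicographically smaller
#' member; strand-agnostic composition is the standard signature used for
#' genome binning.
#'
#' @return Named list with `classes` (character vector of 136 class
#'   representatives, sorted) and `map` (integer vector of length 256 mapping
#'   every 4-mer, in `Biostrings` alphabetical order, to its class index).
#' @export
canonical_tetramers <- function() {
  if (!is.null(.tetramer_cache$tbl)) {
    return(.tetramer_cache$tbl)
  }
  bases <- c("A", "C", "G", "T")
  kmers <- apply(expand.grid(bases, bases, bases, bases)[, 4:1], 1, paste0,
                 collapse = "")
  kmers <- sort(kmers) # Biostrings oligonucleotideFrequency column order
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers))
  )
  rep_kmer <- ifelse(kmers <= rc, kmers, rc)
  classes <- sort(unique(rep_kmer))
  stopifnot(length(classes) == 136L)
  tbl <- list(classes = classes, map = match(rep_kmer, classes))
  .tetramer_cache$tbl <- tbl
  tbl
}

#' Canonical tetramer frequency profile of one sequence
#'
#' Counts every 4-mer window that contains no ambiguous base, pools each
#' 4-mer with its reverse complement, and normalizes the 136 class counts to
#' frequencies. Sequences shorter than 4 bp, or whose windows all contain N,
#' yield the all-zero profile.
#'
#' @param sequence A single character string or [Biostrings::DNAString] over
#'   `{A,C,G,T,N}`.
#' @return Numeric vector of length 136 named by class representative;
#'   entries sum to 1 when at least one valid window exists.
#' @examples
#' p <- tetramer_frequencies("AAAATTTT")
#' p[["AAAA"]] # AAAA and TTTT pooled
#' @export
tetramer_frequencies <- function(sequence) {
  if (is.character(sequence)) {
    sequence <- Biostrings::DNAString(sequence)
  }
  counts <- Biostrings::oligonucleotideFrequency(sequence, width = 4L)
  tbl <- canonical_tetramers()
  collapsed <- as.numeric(
    rowsum(as.numeric(counts), tbl$map, reorder = TRUE)
  )
  names(collapsed) <- tbl$classes
  tot <- sum(collapsed)
  if (tot > 0) collapsed / tot else collapsed
}

#' Tetramer feature matrix for a contig set
#'
#' @param contigs Contig table from [read_contigs()] (columns `id`,
#'   `sequence`).
#' @return Numeric matrix, one row per contig (rownames = contig ids), 136
#'   columns.
#' @export
tetramer_matrix <- function(contigs) {
  stopifnot(is.data.frame(contigs), all(c("id", "sequence") %in% names(contigs)))
  tbl <- canonical_tetramers()
  if (nrow(contigs) == 0L) {
    return(matrix(0, 0, 136, dimnames = list(NULL, tbl$classes)))
  }
  dss <- Biostrings::DNAStringSet(contigs$sequence)
  counts <- Biostrings::oligonucleotideFrequency(dss, width = 4L)
  collapsed <- counts %*% outer(tbl$map, seq_len(136L), "==")
  colnames(collapsed) <- tbl$classes
  tot <- rowSums(collapsed)
  out <- collapsed / ifelse(tot > 0, tot, 1)
  rownames(out) <- contigs$id
  out
}

#' Read contigs from a FASTA file
#'
#' Reads a (possibly gzipped) multi-FASTA assembly. The contig id is the
#' first whitespace-delimited token of each header. Sequences are uppercased
#' and any IUPAC ambiguity codes are mapped to N. Contigs shorter than
#' `min_length` are dropped.
#'
#' @param fasta_path Path to a FASTA file.
#' @param min_length Minimum contig length to retain (bp); default 1000.
#' @return A data frame with columns `id`, `sequence`, `length`, `parent_id`
#'   (NA for original contigs), in file order.
#' @export
read_contigs <- function(fasta_path, min_length = 1000L) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  dss <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(dss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate contig id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  keep <- Biostrings::width(dss) >= min_length
  dss <- dss[keep]
  ids <- ids[keep]
  seqs <- if (length(dss)) {
    as.character(Biostrings::replaceAmbiguities(dss, new = "N"))
  } else {
    character(0)
  }
  data.frame(
    id = ids,
    sequence = unname(seqs),
    length = nchar(seqs),
    parent_id = rep(NA_character_, length(ids)),
    stringsAsFactors = FALSE
  )
}

#' Assemble the network input features
#'
#' Concatenates the 136 canonical tetramer frequencies with the preprocessed
#' abundance columns; this is the input representation of each contig for the
#' embedding network.
#'
#' @param contigs Contig table.
#' @param transformed_abundance Numeric matrix (contigs x samples) of
#'   preprocessed abundances, rownames = contig ids.
#' @return Numeric matrix contigs x (136 + n_samples).
#' @export
feature_matrix <- function(contigs, transformed_abundance) {
  tnf <- tetramer_matrix(contigs)
  ab <- as.matrix(transformed_abundance)
  if (is.null(rownames(ab))) {
    stop("transformed_abundance must have contig ids as rownames")
  }
  missing <- setdiff(contigs$id, rownames(ab))
  if (length(missing) > 0L) {
    stop("abundance missing for contig(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  ab <- ab[contigs$id, , drop = FALSE]
  colnames(ab) <- paste0("abund_", seq_len(ncol(ab)))
  cbind(tnf, ab)
}
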