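Package: contrabin
Title: Self-Supervised Contrastive Binning of Metagenomic Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Groups assembled metagenomic contigs into genome bins. Contigs are
    represented by canonical tetranucleotide frequencies and preprocessed
    per-sample abundances; a siamese neural network trained with a contrastive
    loss on self-supervised must-link (contig break-up) and cannot-link (random
    pairing) constraints maps them into a 100-dimensional embedding. Short-read
    assemblies are clustered via a sparse similarity graph and Infomap community
    detection with marker-gene-guided weighted k-means reclustering; long-read
    assemblies via an ensemble of DBSCAN runs over an epsilon ladder, integrated
    greedily using single-copy marker-gene completeness/contamination scores.
    Includes a ground-truth community simulator and bin evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    Rcpp,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
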