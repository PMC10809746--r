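Package: anchorclust
Title: Anchor-Based Clonal Clustering of Immune Repertoire Junction Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scalable grouping of clonally related B-cell receptor junction
    nucleotide sequences. Maximally spaced anchor sequences are selected with a
    greedy lexicode point-packing algorithm inside a small evolutionary loop,
    every sequence is embedded as a vector of normalized Hamming distances to
    the anchors, the embedding is recursively partitioned with an incremental
    clustering-feature (BIRCH-style) model until each part is small enough for
    all-pairs comparison, and each part is finished with single-linkage
    clustering under a normalized Hamming-distance cutoff. Includes AIRR-style
    TSV and FASTA input, V/J gene-usage grouping before or after clustering,
    pairwise sensitivity/precision/F-measure and label-purity evaluation
    metrics, and a simulator for clonally structured repertoires with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
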