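Package: bplaClust
Title: Clustering of Noncoding RNAs from Ensembles of Sequence Alignments
    and Secondary Structures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Similarity measures for noncoding RNA sequences based on the
    local alignment kernel, a Smith-Waterman variant that sums over all
    local sequence alignments, with position match scores taken as
    expectations over each sequence's Boltzmann ensemble of secondary
    structures (base-pairing probability profiles in the style of the
    McCaskill algorithm). Includes the square-root (BPLA) scoring variant
    and a sequence-only baseline, WPGMA hierarchical clustering of the
    resulting distance matrices, pairs-based ROC/AUC evaluation of cluster
    trees against reference families, and a synthetic benchmark generator
    producing structured RNA families with dinucleotide-matched flanking
    regions and unrelated decoy sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    optparse,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
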