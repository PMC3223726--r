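Package: panregulon
Title: Comparative Reconstruction of Transcriptional Regulons Across
    Bacterial Pangenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative-genomics reconstruction of bacterial
    transcriptional regulons: ortholog detection by Smith-Waterman
    bidirectional best hits, iterative palindrome-seeded discovery of
    transcription-factor binding motifs, position-weight-matrix site
    scanning with a training-set-minimum threshold, a cross-genome
    consistency filter, propagation of known regulons to related genomes,
    ab initio inference of novel regulons, and comparative analytics over
    the resulting regulatory network (conservation classes, regulon
    overlap, expression-correlation subregulons). A seeded pangenome
    simulator with full ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    igraph,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
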