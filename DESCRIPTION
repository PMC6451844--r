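Package: conmir
Title: Homology-Based Discovery of Conserved Plant miRNAs from Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for homology-based identification of
    conserved microRNAs in plant small RNA sequencing data. Covers adapter and
    quality trimming of small RNA reads, collapsing to unique sequences,
    classification against known RNA classes, Smith-Waterman homology search
    against a mature miRNA reference with identity and Karlin-Altschul E-value
    filters, extraction of candidate precursor windows from genome scaffolds,
    weighted Nussinov stem-loop folding and classification, psRNATarget-style
    complementarity scoring of transcript target sites with cleavage versus
    translational-inhibition calls, stress-conservation analysis across
    species evidence tables, and composition / GO reporting. A seeded
    synthetic-data generator produces all pipeline inputs with known ground
    truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    withr,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
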