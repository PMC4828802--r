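Package: srnapipe
Title: Small RNA and Degradome Sequencing Analysis for Plant miRNA Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-style implementation of a combined small
    RNA-seq and degradome (PARE) analysis for discovering drought-responsive
    microRNAs in plants. Provides read cleaning and collapsing, exact genome
    mapping and Rfam-style annotation with a fixed precedence, known and
    novel miRNA identification under explicit hairpin, duplex, energy and
    locus-count criteria, a per-pair energy Nussinov folding engine, TPM
    normalisation with Audic-Claverie, Fisher and chi-square differential
    expression tests, degradome T-plot construction with Allen-style
    complementarity scoring and five-category cleavage-site classification,
    and a seeded synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
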