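Package: translatome
Title: Transcriptome and Translatome Reprogramming Analysis from Paired
    mRNA-Seq and Ribo-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired mRNA-seq and ribosome-profiling
    (Ribo-seq) count tables across a time course of endoplasmic-reticulum
    stress. Computes RPKM, a strict all-replicates detection filter, and
    per-condition ribosome occupancy (mean Ribo-seq RPKM over mean mRNA-seq
    RPKM); derives log2 differential expression (L2DE) contrasts; assigns
    transcripts to twelve temporal regulation groups (G1-G12) and four joint
    transcriptional/translational regulation modes by fold-change threshold
    rules; derives cell-type-specific stress gene sets (regulome, adaptome)
    with hypergeometric over-representation tests and rank-sum cross-cohort
    comparisons; performs Ribo-seq reading-frame and CDS-enrichment quality
    control; and ships a negative-binomial synthetic-data generator with
    planted ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
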