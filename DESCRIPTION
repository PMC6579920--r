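Package: mobilomeR
Title: Bacterial Pan-Genome and Mobilome Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative analysis of bacterial genomes with a
    focus on mobile genetic elements. Clusters predicted proteins into
    orthologous groups and derives pan- and core-genome curves, the k-genome
    spectrum and ORFans; discovers insertion sequences from multi-copy
    transposase annotations, delimits their terminal inverted repeats and
    calls composite transposons; detects cross-species homology blocks as
    putative horizontal gene transfer regions and maps plasmid-to-chromosome
    integrations; characterizes genomic islands as candidate integrative and
    conjugative elements via flanking direct repeats, signature-gene screens
    and in-silico PCR excision tests. A synthetic-genome generator with a
    planted-truth ledger makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
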