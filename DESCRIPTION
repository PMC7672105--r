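Package: atacreg
Title: Downstream Analysis of Multi-Cell-Type ATAC-Seq Regulomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the downstream analysis of
    ATAC-seq peak count matrices collected across multiple cell types and
    clinical states. Implements quantile normalization and log2 intensity
    transforms, peak-to-gene annotation, one-vs-rest cell-type-specific
    peak calling with coefficient-of-variation filters, six-state
    classification of differential peaks across normal, clinically
    unaffected and affected tissue, deviation-score enrichment of
    trait-associated SNPs in accessible chromatin, cell-type signature
    scoring of expression data with clinical-score correlation, Tn5
    insertion footprint aggregation around transcription-factor motif
    sites, hypergeometric motif enrichment, and receptor-ligand
    strength-of-interaction-alteration (SIA) scoring of intercellular
    communication. A seeded synthetic-data generator with machine-readable
    ground truth makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
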