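Package: polysomics
Title: Translatome Analysis of Paired Total and Polysomal RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing polysome-profiling experiments in which a
    total-mRNA library and a polysomal-mRNA library are sequenced for two
    conditions (e.g. presenescent and senescent fibroblasts) without
    biological replicates. Provides a negative-binomial simulator with known
    per-gene transcriptional and translational fold changes, trimmed mean of
    M-values (TMM) scaling factors and FPKM conversion, an exact conditional
    test for single-library two-condition contrasts with Benjamini-Hochberg
    correction, cross-classification of genes into transcriptional versus
    translational regulation, a 5'UTR scanner for TOP and TOP-like
    pyrimidine tracts, and the bench-validation arithmetic used to confirm
    such results (spike-normalized 2^-ddCt quantification, population
    doubling curves, SA-beta-gal positive rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
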