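Package: tmzscreen
Title: CRISPR Dropout Screen Statistics and Temozolomide Mutational
    Signature Analysis for Glioblastoma Chemoresistance Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for the computational analyses used
    in studies of temozolomide (TMZ) chemoresistance in glioblastoma: gene-
    and pathway-level dropout statistics for DNA-damage-response (DDR)
    focused pooled CRISPR screens (SigmaFC gene ranking, permutation
    p-values against non-targeting controls, two-sample gene Z-statistics
    and their pathway-level combination), a somatic-variant post-calling
    filter chain with 96-trinucleotide mutation catalogs and Pattern I/II
    decomposition, COSMIC-style signature refitting by non-negative least
    squares with a Signature-11 hypermutation classifier and Tukey-adjusted
    group comparisons, and a patient-cohort model linking
    proliferation-adjusted RAD18 expression to hypermutation. A synthetic
    data module generates every input (sgRNA libraries, screen counts and
    cassette reads, per-clone mutation catalogs with known signature
    exposures, patient cohorts) with ground truth retained, so the whole
    pipeline runs and is testable without external downloads.
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
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
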