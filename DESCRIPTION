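Package: pairsig
Title: Paired Tumor and Adjacent-Tissue Prognostic Gene Signatures
Version: 0.1.0
Authors@R: person("pairsig", "developers", role = c("aut", "cre"),
    email = "pairsig@example.org")
Description: Survival-optimal dichotomization of gene expression (1-D
    data-driven grouping), selection of common prognostic genes across
    paired primary-tumor and adjacent non-malignant tissue, a statistically
    weighted voting multigene risk classifier with frozen-parameter
    cross-cohort validation, combined tumor-and-adjacent stratification,
    agreement and overlap statistics (Newcombe-Wilson score intervals,
    hypergeometric overlap), differential expression and gene-set
    correlation profiling, and a seeded generator of paired censored
    survival cohorts for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    survival,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
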