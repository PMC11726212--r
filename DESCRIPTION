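Package: adattn
Title: Grouped Dot-Product Attention Models for Multi-Label Alzheimer's
    Subtype and Severity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a modular neural model for multi-label diagnosis of
    Alzheimer's disease subtypes (logopenic variant, posterior cortical
    atrophy, frontal variant) from tabular clinical data.  Laboratory
    features are grouped into clinically meaningful modules, each processed
    by scaled dot-product self-attention over per-feature token embeddings;
    pooled context vectors are fused with directly supplied neurological
    markers and passed through fully connected layers to three severity
    outputs in [0, 1].  Ships the full surrounding protocol: a feature
    schema with clinical reference ranges, reference-range min-max
    normalization, mean imputation, leakage-safe train/validation/test
    splitting, SMOTE minority oversampling, a parameter-matched
    fully-connected baseline, ordinal severity binning and evaluation
    reports, and a seeded synthetic-cohort generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
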