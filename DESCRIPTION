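Package: markerscan
Title: Bootstrap Cutoff Selection and Multifactorial Survival Analysis of
    Tumor Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for ranking continuous tumor biomarkers by their impact on
    time-to-event outcomes in chemo-radiotherapy cohorts. Implements
    single-sample gene-signature scoring (TPM single-gene, rank-z gene-set and
    set-ratio scores), construction of locoregional control, distant
    metastasis, overall and progression-free survival endpoints with
    death-censoring semantics, a fast Efron-tie Cox proportional-hazards
    engine, bootstrap-based robust dichotomization cutoff selection with
    moving-average smoothing and minimum-group-size constraints, backward
    model selection by AIC, and cutoff-averaged hazard-ratio marker profiles.
    Includes a Gaussian-copula synthetic cohort generator with known ground
    truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    generics,
    Rcpp,
    survival,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
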