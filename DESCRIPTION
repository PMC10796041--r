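Package: mdci
Title: Multidimensional Diagnosis-Based Comorbidity Index from Hospital Register Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates a multidimensional diagnosis-based comorbidity
    index (MDCI) from longitudinal ICD-10 diagnosis histories. Raw codes are
    normalized and expanded to four granularity levels (2-5 characters), filtered
    by cohort prevalence, and turned into ten binary predictors per code variant
    describing occurrence, frequency, recency, and total duration of hospital
    admission over a lookback window. A cross-validated elastic-net Cox model for
    all-cause mortality selects predictors and weights; subjects are scored and
    categorized into development-cohort quartiles. Includes a Charlson comorbidity
    index comparator, a validation suite (Harrell concordance with bootstrap
    confidence intervals, calibration curves, Kaplan-Meier stratification,
    stratified hazard ratios, index correlations), and a synthetic hospital
    register simulator whose mortality hazard genuinely depends on occurrence,
    frequency, recency, and duration features, so the full pipeline can be
    exercised without access to patient registers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    Matrix,
    glmnet,
    survival,
    jsonlite,
    ggplot2,
    generics,
    Rcpp,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
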