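Package: misutilizr
Title: Forensic Assessment of Hospital Resource Misutilization from
    Administrative Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Risk-adjusts a binary in-patient resource-use outcome (a CT of
    the pelvis/abdomen without contrast, in the motivating prostate-cancer
    cohort) on patient characteristics and competing imaging resources via
    multivariate logistic regression, compares model discrimination with
    DeLong's test, calibrates a decision-curve threshold to industry-average
    utilization intensity, labels each visit as concordant, over-, or
    under-utilized, quantifies disparities in misutilization through odds
    ratios, and flags outlying facilities with volume-adjusted exact Poisson
    rate tests. Includes a synthetic administrative-cohort generator
    (Gaussian-copula competing resources, log-normal facility volumes,
    planted outlier facilities) so the full pipeline is reproducible without
    access to proprietary claims data.
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
    mvtnorm,
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
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
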