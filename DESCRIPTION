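Package: dtprog
Title: Discrete-Time Survival Analysis of Multi-Stage Training Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing annual progression through ordered,
    multi-stage training programmes with discrete-time survival methods.
    Builds person-period datasets from annual observation records, fits a
    logistic hazard model with time dummies entered as intercepts, derives
    per-transition hazards, cumulative survival curves, odds ratios with
    Wald confidence intervals, likelihood-ratio tests and pseudo R-squared
    statistics, and cross-checks results against actuarial life tables and
    the Kaplan-Meier product-limit estimator. Includes a configurable
    synthetic cohort generator emulating a national training registry
    (entry cohorts, per-transition hazards, covariate effects on the
    hazard logit, administrative right censoring, stayer duplication and
    covariate missingness) and statistical disclosure control for
    published counts, percentages and averages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
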