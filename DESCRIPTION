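Package: claimscast
Title: Temporal Persistence and Forecasting of Health Care Expenditures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates longitudinal insurance-claims panels with controllable
    temporal structure, quantifies the month-to-month and year-to-year
    persistence of patient-level expenditures, and forecasts per-member
    per-month spending with four model families: ordinary least squares,
    L1-regularized regression fit by cyclic coordinate descent, second-order
    gradient-boosted regression trees, and a dual-attention gated recurrent
    unit network. Every prediction can be decomposed into additive
    per-input-variable contributions, with bootstrap estimates of how stable
    those contributions are under refitting. A rolling train-on-t,
    test-on-t+1 harness evaluates the models on rank-percentile error with a
    dedicated top-decile (high-cost, high-need) error measure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    xgboost
Config/testthat/edition: 3
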