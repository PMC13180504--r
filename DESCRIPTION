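Package: rmstsculpt
Title: Two-Stage Double-Arm Trial Design with Sculpted RMST Critical Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of two-stage double-arm phase II survival
    trials that test superiority on the restricted mean survival time (RMST)
    scale with a sculpted rejection region: the null is rejected only when both
    the between-arm RMST difference and the experimental-arm RMST exceed
    stage-specific critical values. Provides patient-level trial simulation
    under proportional and non-proportional (piecewise-exponential) hazards
    with uniform accrual and censoring, Kaplan-Meier RMST estimation with
    Greenwood-type variance, Monte-Carlo calibration of stage-wise critical
    values through an interim-sample-size control function and truncated
    bivariate-normal conditional moments, empirical operating characteristics,
    minimax and optimal (minimum expected-null-sample-size) design search, and
    a grid-searched two-stage log-rank comparator.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
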