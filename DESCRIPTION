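Package: rsigcut
Title: Mortality Cutpoints for the Reverse Shock Index Multiplied by the
    Glasgow Coma Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives and evaluates in-hospital-mortality cutoffs for the
    reverse shock index multiplied by the Glasgow Coma Scale (rSIG) in
    adult trauma cohorts. Provides a synthetic trauma-registry generator
    with a planted ground-truth risk curve, registry cleaning and
    inclusion filtering with flow accounting, shape-restricted (monotone
    I-spline) binomial regression of mortality against rSIG with analytic
    derivatives, extraction of onset and maximal-slope-change points,
    Youden-index cutoffs, rank-based ROC/AUC with DeLong confidence
    intervals, under-/over-triage evaluation against American College of
    Surgeons targets, univariable and multivariable logistic odds-ratio
    tables, and an end-to-end subgroup analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
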