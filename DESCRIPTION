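Package: olaparibCEA
Title: Cost-Effectiveness of Adjuvant Olaparib in Germline BRCA-Mutated
    Early Breast Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Markov cohort state-transition model comparing one year of
    adjuvant olaparib with no olaparib for high-risk, early-stage breast
    cancer with a germline BRCA1/2 pathogenic variant. Provides
    survival-to-rate conversions, iterative calibration of year-specific
    metastatic-recurrence rates to trial distant disease-free and overall
    survival targets, a lifetime four-state monthly-cycle cohort engine
    with discounted cost, life-year and QALY accrual, incremental
    cost-effectiveness analysis, one-way sensitivity analysis with
    threshold search, and second-order probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
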