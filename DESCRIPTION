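Package: markovcea
Title: Markov Cohort Cost-Effectiveness Analysis for Two-Arm Treatment
    Comparisons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and runs three-state (progression-free, progressed,
    dead) Markov cohort models for cost-effectiveness analysis of two-arm
    oncology treatment comparisons. Derives monthly transition
    probabilities from median progression-free and overall survival under
    a constant-hazard assumption, propagates a cohort over a monthly-cycle
    horizon with discounted cost and QALY accrual, computes incremental
    cost-effectiveness ratios and net monetary benefit against a
    willingness-to-pay threshold, and quantifies uncertainty through
    one-way deterministic (tornado) and probabilistic (Monte Carlo)
    sensitivity analyses with cost-effectiveness acceptability curves.
    Includes a synthetic trial-data generator for end-to-end validation
    and a packaged parameter set for a published comparison of
    bevacizumab plus lomustine versus lomustine in progressive
    glioblastoma.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
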