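Package: netbenefit
Title: Generalized Pairwise Comparisons for Prioritized Endpoints in Two-Arm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritized generalized pairwise comparison (GPC) analysis for
    two-arm clinical trials with mixed endpoint types: censored time-to-event
    endpoints compared with a clinical-relevance margin under Gehan-style
    scoring, binary response, and ordinal quality-of-life and toxicity
    endpoints. Every patient in one arm is compared with every patient in the
    other on a ranked endpoint hierarchy; undecided pairs cascade to the next
    endpoint. Reports the net treatment benefit, win ratio, per-level
    decomposition and conditional win probabilities, with stratified bootstrap
    confidence intervals and arm-label permutation p-values. Includes EORTC
    QLQ-C30/CR29 scale scoring with change-from-baseline classification,
    follow-up toxicity tables, Kaplan-Meier and Aalen-Johansen summaries at
    fixed horizons, and a seeded synthetic two-arm cohort generator for
    testing and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    jsonlite,
    ggplot2,
    survival,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
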