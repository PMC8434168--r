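Package: exerscreen
Title: Stealth Cognitive Screening from Exergame In-Game Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for stealth assessment of
    cognitive status from exergame telemetry in older adults. Generates a
    synthetic three-group cohort (cognitively normal, mild cognitive
    impairment, mild dementia) with longitudinal session telemetry across
    five exercise domains and five high-resolution monitoring games;
    computes weighted in-game scores on a 10-point scale; extracts
    mean/slope/intercept trend features per difficulty level; and runs the
    screening battery: Kruskal-Wallis with epsilon-squared effect sizes and
    Dunn-Bonferroni post-hoc tests, Pearson correlations against
    neuropsychological instruments, correlation-based feature-subset
    selection with best-first search, a multilayer-perceptron classifier
    under stratified cross-validation, and ROC/AUC cutoff screening for
    mild cognitive impairment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    nortest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
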