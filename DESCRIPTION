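Package: sipheno
Title: Rule-Based Phenotyping and Machine-Learning Calibration of Statin
    Intolerance in Outpatient EMR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the prevalence of statin intolerance from
    longitudinal outpatient electronic medical records. Implements a rule
    engine that detects statin-intolerance signal events (down-titration,
    switch, multi-statin use, discontinuation, intermittent dosing, low-dose
    use, documented intolerance, statin-associated muscle symptoms) over a
    patient-level lookback window and classifies patients into absolute or
    partial intolerance at high or low confidence; a supervised-learning
    calibration step that trains high-confidence-versus-tolerant classifiers,
    tunes the decision threshold to the precision-equals-recall point, and
    reclassifies low-confidence patients to update the prevalence table; and a
    synthetic EMR generator with planted ground-truth phenotypes for testing
    every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
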