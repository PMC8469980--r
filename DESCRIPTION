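Package: frailscreen
Title: Scoring and Diagnostic Validation of Brief Frailty Screening Scales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores the six-item binary Zulfiqar Frailty Scale (ZFS) and the
    thirteen-item modified SEGA grid A (0/1/2 ordinals, total /26), and
    provides the full diagnostic-validation machinery used to assess a
    screening scale against a reference frailty definition: 2x2
    contingency metrics (sensitivity, specificity, predictive values,
    Youden index) with Wilson confidence intervals, risk ratios with Katz
    log-method intervals, association tests (Fisher exact or Yates
    chi-square by expected-count rule), ROC cut-point tables with
    tie-corrected AUC and optimal-threshold selection, reconstruction of
    score-by-group distributions from published cumulative ROC tables,
    Pearson item/total correlations with Fisher-z intervals, and a seeded
    latent-factor (Gaussian copula) simulator for correlated binary and
    ordinal questionnaire cohorts. Includes delimited-file cohort I/O, a
    consolidated validation report, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
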