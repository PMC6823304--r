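Package: tachyrisk
Title: Predicting Tachycardia Episodes from ICU Vital-Sign Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects clinically defined tachycardia episodes (heart rate at or
    above a threshold, minimum duration and duty cycle) from minute-level ICU
    vital-sign records, builds case/control 30-minute analysis windows for
    three modeling designs, computes 42 window features (means, variability,
    regression slopes, spectral power with spline gap-filling, autocorrelation,
    approximate and sample entropy, record density), trains cross-validated
    lasso logistic regression and random forest risk models, and produces
    minute-by-minute risk trajectories and patient-specific lift scores.
    Includes a seeded multichannel vital-sign simulator with ground-truth
    episodes so the full pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pracma,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
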