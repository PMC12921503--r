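Package: teamjudge
Title: Confidence-Weighted Combination of Human and Machine Judgments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for combining the judgments of human and machine team
    members on classification and forecasting tasks. Implements a
    confidence-weighted logistic combination model for any number of
    teammates and any number of classes, a two-member Bayesian combination
    model with correlated latent probability scores, a temperature-softmax
    choice likelihood and an ordered-logistic confidence likelihood,
    grouped leave-one-out cross-validation over all team subsets, shuffle
    controls, calibration and diversity diagnostics, and a synthetic
    judgment-panel simulator with controllable accuracy, confidence
    calibration and inter-agent diversity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
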