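Package: mheval
Title: Joint Decision-Tree and Neural-Network Models for Mental-Health
    Assessment Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying tabular mental-health assessment records
    with a C4.5 decision tree whose information-gain-ratio computation is
    replaced by third-order Maclaurin polynomial approximations of the
    logarithm (TAM-C4.5), a multilayer perceptron trained either by
    gradient descent on softmax cross-entropy or by the
    Levenberg-Marquardt rule on sum-squared error, and a soft-vote joint
    model combining the two. Includes equal-division-point discretization
    of continuous attributes, a deterministic synthetic-data generator
    emulating questionnaire-plus-activity records, MAE/MSE/RMSE/MAPE and
    recall evaluation, and a model-comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
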