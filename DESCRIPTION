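Package: fcmrisk
Title: Fuzzy Cognitive Map Decision Support for Gastric Cancer Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Medical decision support for three-level gastric cancer risk
    stratification built on fuzzy cognitive maps (FCMs). Expert linguistic
    causal judgments are aggregated by pointwise summation of triangular
    membership functions and defuzzified by the centroid rule into a signed
    weight matrix; patient records drive synchronous sigmoid FCM inference to
    a steady state whose output-concept activation is thresholded into
    low/medium/high risk. Weights are refined by Nonlinear Hebbian Learning
    (NHL) with dual termination criteria (squared distance of output
    concepts from class-target midpoints, and consecutive-iteration change
    below a tolerance), including a learning-rate/decay grid search. Ships
    a 28-concept, 38-edge gastric cancer map, a synthetic cohort generator
    matching published per-feature marginal frequencies, the full
    three-class confusion-matrix metric suite (accuracy, recall, precision,
    MAE, RMSE) with truncation-style reporting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
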