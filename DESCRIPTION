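Package: sgefafire
Title: Seasonal Fire Drivers and Predictability via Lagged-Covariance
    Feedback Assessment and Machine Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the instantaneous response of a fast ecological
    variable (regional fire carbon emission or burned-area fraction) to
    slowly evolving oceanic and terrestrial forcings with the stepwise
    Generalized Equilibrium Feedback Assessment (SGEFA): lagged-covariance
    response estimation, backward-stepwise AIC forcing selection, and
    Monte-Carlo permutation significance. Couples the identified forcings
    to a seasonal prediction system built from five machine-learning
    families (random forest, support-vector regression, feed-forward
    neural network, L1-penalized regression, gradient boosting) evaluated
    over repeated random train/test splits. Ships a synthetic-data
    generator with known feedback coefficients, monthly-anomaly and
    detrending preprocessing, basin EOF decomposition of sea-surface
    temperature, and pipeline drivers that write reproducible tabular
    outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    ranger,
    e1071,
    nnet,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
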