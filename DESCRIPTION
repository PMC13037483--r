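Package: gcqsrr
Title: Quantitative Structure-Retention Relationship Modelling for Gas
    Chromatography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts gas-chromatographic retention times of small
    molecules from molecular descriptors. Implements the full QSRR
    workflow: descriptor pre-treatment (constant, near-constant and
    collinearity filters with train-set autoscaling), genetic-algorithm
    wrapper descriptor selection with a penalized cross-validated
    fitness and multi-run consensus, NIPALS partial least squares,
    RBF kernel partial least squares, and a single-hidden-layer
    perceptron trained by Levenberg-Marquardt with validation-based
    early stopping, restart stability analysis and perturbation
    sensitivity analysis. Includes leave-group-out cross-validation,
    an external-test metric suite, a packaged retention-time dataset
    of 75 narcotic and hazardous drugs, and a synthetic-data generator
    with known ground truth for benchmarking descriptor selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
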