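Package: uqens
Title: Subsampling-Ensemble Uncertainty Quantification for Molecular
    Property Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds subsampling ensembles for quantitative
    structure-activity regression by repeated k-fold cross-validation
    (or bootstrapping), aggregates the out-of-sample member predictions
    into an ensemble point estimate and a standard-deviation
    uncertainty, and evaluates both with the cross-validated coefficient
    of determination and the Spearman rank correlation between
    uncertainty and absolute error.  Includes molecular featurization
    through substructure-key counts, hashed circular-substructure
    counts and physicochemical descriptors; model adapters for random
    forests, gradient-boosted trees, support vector machines and small
    multilayer perceptrons with Monte Carlo dropout; rank-sum comparison
    across featurization-by-technique grids; a growing-ensemble
    saturation analysis based on permutation-smoothed cumulative member
    curves and Michaelis-Menten fits; and a synthetic-data generator
    with controllable heteroscedastic noise for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    e1071,
    jsonlite,
    minpack.lm,
    randomForest,
    rlang,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
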