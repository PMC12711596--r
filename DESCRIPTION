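Package: ensdm
Title: Ensemble Species Distribution Modelling with Bias-Corrected
    Pseudo-Absences and Scenario Projection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ensemble species distribution modelling on gridded
    landscapes: occurrence cleaning and grid-based spatial thinning,
    environmental-envelope pseudo-absence generation with survey-effort
    bias correction, iterative variance-inflation-factor predictor
    screening, a multi-algorithm ensemble (GLM, GAM, MARS, GBM, ANN, RF,
    MAXENT, SRE, CTA, FDA) combined by TSS-weighted averaging, projection
    onto averaged future-climate predictor stacks with habitat-change
    classification, and overlay accounting of suitable habitat against
    zone polygons and wind-farm footprints.  Includes a synthetic
    landscape generator with controllable collinearity, a known true
    suitability surface and an observer-accessibility bias field, so the
    whole workflow can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    mgcv,
    nnet,
    randomForest,
    rpart,
    xgboost,
    glmnet,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
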