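Package: mosr
Title: Multi-Objective Symbolic Regression for Perioperative Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolves readable mathematical formulae for binary clinical
    classification by genetic programming under a joint accuracy/complexity
    objective (binary cross-entropy and a complexity-penalised AIC), with
    NSGA-II style Pareto selection. Includes cardiopulmonary exercise test
    (CPET) signal processing (median filtering, shape-preserving
    downsampling, V-slope anaerobic threshold detection, 30-second peak
    oxygen uptake), a synthetic perioperative cohort generator with POMS
    morbidity outcomes and 1-Hz exercise waveforms, threshold-based clinical
    score baselines and reference classifiers, a leakage-safe evaluation
    protocol (stratified splits, cross-validated grid search, repeated
    test-set subsampling with confidence intervals), and model-agnostic
    Shapley feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rpart,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
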