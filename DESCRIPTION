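Package: uamtox
Title: Uncertainty-Aware Prediction of Toxicological Points of Departure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Uncertainty-aware machine learning for predicting toxicological
    points of departure (PODs) with calibrated 95% confidence intervals.
    Provides chemical-structure standardization and unit conversion,
    molecular featurization (MACCS keys, circular Morgan-type fingerprints,
    2D physicochemical descriptors, ingested learned embeddings) with
    leakage-free fold-wise preprocessing, an uncertainty-aware conformalized
    quantile-regression-forest (UACQR) regressor, a mean-field variational
    Bayesian neural network with heteroscedastic Gaussian output, a
    three-part uncertainty-calibration suite (confidence-based ECE,
    error-based ENCE with entropy-based batching, distance-based Jaccard
    k-nearest-neighbour diagnostics), stratified repeated cross-validation
    with paired significance testing and consensus baselines, chemical-library
    screening with class-level potency ranking, and a synthetic
    structure-toxicity data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    caret,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    glmnet,
    nnet,
    xgboost,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
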