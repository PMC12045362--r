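Package: biospike
Title: Biophysical GCaMP Modelling and Spike Inference from Calcium Fluorescence
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A biophysical generative framework for calcium-indicator
    fluorescence and spike inference. Models GCaMP-family sensors as a
    nine-state kinetic scheme (calcium binding at the two calmodulin lobes,
    each followed by target-peptide binding to a fluorescent state), coupled
    to a single-bouton calcium-handling model with linearized endogenous
    buffering, Michaelis-Menten extrusion, store exchange, and a slow
    compartment. Provides stopped-flow simulation and calibration machinery
    (multi-exponential, Hill, and multistart global fits), particle Gibbs
    with ancestor sampling (PGAS) for joint Bayesian inference of spike
    times and cell parameters, a linear autoregressive baseline model, a
    supervised regressor trained on synthetic traces, a synthetic-data
    generator with ground truth, and a spike-matching evaluation suite
    (linear-assignment matching, F-score, timing bias and uncertainty,
    filtered correlations, robust summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    lhs,
    xgboost,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'sensor-kinetics.R'
    'stopped-flow.R'
    'cell-model.R'
    'calibration.R'
    'io.R'
    'smc-inference.R'
    'spike-metrics.R'
    'supervised.R'
    'synthetic-data.R'
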