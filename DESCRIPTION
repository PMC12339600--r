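Package: itcnet
Title: Amortized Inference and Likelihood-Based Benchmarks for
    Intertemporal Choice Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for fitting and comparing cognitive models of
    intertemporal (delay-discounting) choice. Implements three choice
    models (hyperbolic, hyperboloid, and attribute-wise direct
    difference), synthetic-participant simulators for the 27-item
    monetary choice questionnaire and for variable-length randomized
    designs, simulation-inversion neural networks (feed-forward and
    recurrent/LSTM) for amortized parameter estimation and model
    classification, Monte-Carlo-dropout posterior sampling, and a
    likelihood-based benchmark built on adaptive Metropolis MCMC with
    DIC, WAIC, AIC, BIC and log-likelihood model-recovery scoring,
    confusion matrices and calibration curves.
License: GPL-3
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
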