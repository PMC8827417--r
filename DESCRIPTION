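Package: sparsebalance
Title: Sparse Balance Excitatory-Inhibitory Rate Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and mean-field analysis of recurrent rate networks in
    the sparse-balance regime, where an order-one feedforward bias current is
    combined with broadly distributed (high-variance) synaptic weights.
    Provides samplers for gamma, lognormal, Gaussian and binary weight
    matrices with in-degree-dependent moment scalings, a forward-Euler
    integrator with a compiled core for single-population inhibitory and
    two-population excitatory-inhibitory networks, the summary statistics that
    characterize the regime (mean response, fraction active, temporal and
    quenched variance components, autocorrelation time, decorrelation rate,
    balance and synchrony indices), closed-form gamma-distribution predictions
    for the recurrent synaptic input, a dynamic mean-field theory solver for
    the Gaussian-weight network, and sweep and fitting utilities for power-law
    scaling analyses in the in-degree K.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    pracma,
    e1071,
    nortest,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
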