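Package: ddehm
Title: Hybrid Delay Differential Equation Models of Biochemical Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits hybrid semi-parametric delay differential equation models
    of biochemical networks: mechanistic material balances whose unknown
    kinetic rates are represented by a three-layer feed-forward neural
    network fed with discrete time-lagged state and input values. Training
    uses weighted least squares with analytic gradients obtained from
    forward sensitivity equations integrated alongside the model, random
    multistarts and validation-based early stopping; model structure
    (hidden nodes, delay sets) is selected by the Bayesian information
    criterion. Includes a fixed-step averaged-rate DDE integrator, an
    embedded Runge-Kutta 2(3) integrator with continuous extension, and
    simulators for a delayed transcription-factor autoactivation system
    and a fed-batch Pichia pastoris culture with an Erlang distributed
    delay realised by the linear chain trick.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
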