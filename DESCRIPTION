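Package: togglecbc
Title: Control-Based Continuation of a Genetic Toggle Switch
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Traces stable and unstable equilibrium branches of an
    inducible LacI/TetR genetic toggle switch directly from simulated
    experiments using control-based continuation: a stabilizing,
    noninvasive feedback controller (proportional or model-predictive)
    steps a reference across the output range while the settled constant
    input is read as a shift of the bifurcation parameter. Includes
    deterministic and chemical-Langevin plant models, model-based
    pseudo-arclength continuation with saddle-node detection as the
    reference curve, innovation-form system identification with a Kalman
    predictor for the model-predictive controller, and steady-state
    parameter estimation from collected equilibrium points via an
    analytic inverse and a genetic algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
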