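Package: arbavoid
Title: Dual-System Avoidance Learning with Reliability-Based Arbitration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation, likelihood-based fitting and analysis of a two-step
    pain-avoidance task in which behaviour arises from a model-free SARSA
    learner and a model-based planner whose influence on choice is set
    trial-by-trial by a reliability-based arbitration mechanism. Provides the
    task generator (goal devaluation, two transition-uncertainty levels,
    randomised block scheduling), agent simulation with full latent traces,
    multi-start Nelder-Mead maximum-likelihood estimation of the six model
    parameters, parameter-recovery diagnostics, and the behavioural and
    likelihood-ratio analyses used to dissociate habitual from goal-directed
    control of avoidance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
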