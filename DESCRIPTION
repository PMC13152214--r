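Package: neuroscale
Title: Scaling of Delayed Feedback and Minimum-Time Feedforward Perturbation Responses
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Neuromechanical models of fast perturbation responses in
    terrestrial mammals of different sizes. Implements a delayed
    proportional-derivative feedback controller and a minimum-time bang-bang
    feedforward controller acting on pendulum plants (a distributed-mass
    swing-limb pendulum and a point-mass inverted pendulum for posture),
    with actuator saturation and a sensorimotor deadtime. Provides a
    method-of-steps delay-differential-equation engine, settling-time and
    overshoot response metrics, zero-overshoot gain optimization, switch-time
    optimization, a dimensionless single-free-parameter feedback model with a
    force-capacity sweep and delay-limited/force-limited region
    classification, and an allometric scaling pipeline that materializes
    animal parameters from power laws and fits power laws to response times
    across a ten-size body-mass grid.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
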