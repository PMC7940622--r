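Package: macaquegait
Title: Forward-Dynamic Simulation of Bipedal Locomotion in the Japanese Macaque
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A planar neuromusculoskeletal forward-dynamics simulator of
    bipedal locomotion in the Japanese macaque. A nine-link rigid-body model
    driven by ten principal hindlimb muscle groups is controlled by a two-layer
    central pattern generator (coupled phase oscillators with touchdown phase
    resetting and Gaussian pattern formation) plus trunk posture feedback.
    Muscle activation patterns are tuned by a seeded real-coded genetic
    algorithm minimizing a composite locomotor objective. The package computes
    gait metrics, ground reaction force profiles, muscle mechanical work, gross
    metabolic cost of transport and pendular energy recovery, and implements a
    virtual foot-morphing experiment in which the heel contact point is
    translated inferiorly to convert the digitigrade foot into a plantigrade
    one.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
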