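Package: itcddm
Title: Multi-Attribute Drift Diffusion Modelling of Intertemporal Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying impulsive intertemporal choice with a
    multi-attribute drift diffusion model (DDM). The drift rate is a linear
    function of the money difference and the delay difference between a
    smaller-sooner and a larger-later option. The package provides the
    Wiener first-passage-time density (dual small-time/large-time series),
    trial simulation, maximum-likelihood and Bayesian per-participant
    fitting with posterior-predictive summaries, delay-discounting task
    scoring (titration indifference points, hyperbolic k), group contrasts
    with effect sizes, scale reliability, percentile-bootstrap mediation
    (simple, parallel and serial), and a seeded synthetic-cohort generator
    that emulates smartphone-separation experiments end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    lhs,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
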