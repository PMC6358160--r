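Package: neurobulb
Title: Cortico-Bulbar Network Rewiring by Adult Neurogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Firing-rate simulator of the olfactory bulb and an associative
    cortical area coupled by top-down projections. Granule cells turn over via
    adult neurogenesis with activity-dependent survival, while Hebbian
    plasticity in the cortical network learns odor and context associations.
    The package provides the steady-state solver for the three-population rate
    model, the neurogenic structural-plasticity loop with homeostatic control
    of inhibition, parameterized Gaussian odor scenes, Fisher-discriminant
    performance statistics, and scripted experiments for context-enhanced
    detection and discrimination in cluttered odor environments, memory
    extinction, and cortical task switching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
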