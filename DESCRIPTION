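Package: osteonet
Title: Stochastic Simulation and Mean-Field Analysis of Osteocyte Network
    Formation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of osteocyte network formation during
    bone growth, together with the traveling-wave mean-field theory used to
    calibrate it. Osteoblasts on a moving deposition front secrete bone,
    grow dendritic connections to buried osteocytes, and terminally
    differentiate at a rate that may depend on their network degree
    (null, switch, cumulative or diminishing models). The package provides
    the fixed-time-step Monte Carlo engine, closed-form calibration of the
    differentiation and dendrite-growth rates against healthy-bone targets,
    a transient degree-hierarchy solver, network/density observables,
    a parameter-sensitivity harness, and CSV/GraphML exports with a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
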