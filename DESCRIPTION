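Package: motorlattice
Title: Lattice Monte Carlo and Analytic Models of Collective Molecular
    Motor Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models cargo transport by finite clusters of processive and
    non-processive molecular motors stepping on a one-dimensional lattice
    under a leading-motor load. Provides closed-form force-velocity
    relations, steady-state distributions of the number of bound motors
    with unlimited or limited binding sites, stall forces, and average
    cluster velocities, together with a compiled fixed time-step Monte
    Carlo simulator (simple exclusion, stochastic binding and unbinding,
    fixed or variable sequence-preserving binding windows) and an
    event-driven Gillespie engine used as a cross-validation oracle.
    Includes parameter presets for kinesin-1 and Ncd, experiment drivers
    for force-velocity curves, bound-motor distributions, stall-force and
    run-length studies, and a motor-number inference routine for comparing
    simulated velocity and run-length statistics with tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
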