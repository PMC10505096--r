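Package: permcount
Title: Membrane Permeability from Transition-Based Counting of Bilayer
    Crossings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates passive membrane permeability from unbiased
    molecular-dynamics trajectories by transition-based counting (TBC) of
    complete transbilayer translocation events. Provides a z-coordinate
    time-series container with a plain-text interchange format and an
    optional reader for common trajectory containers, a three-region
    hysteresis detector of crossing events, steady-state rate estimation
    with a derivative plateau criterion, conversion of crossing rates to
    permeability, Boltzmann-inversion free-energy profiles along the
    membrane normal, and a log-log least-squares calibration that maps
    high-temperature simulated permeabilities onto experimental apparent
    permeabilities at 37 degrees Celsius for relative ranking of compounds
    crossing the blood-brain barrier. A one-dimensional overdamped
    Langevin simulator with an analytic mean-first-passage crossing-rate
    oracle supplies ground-truth synthetic data, and the kinetic and
    experimental reference tables for an 18-compound CNS library ship as
    packaged fixtures.
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
    Rcpp
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
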