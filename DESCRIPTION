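Package: twoprocess
Title: Simulation and Entrainment Analysis for the Two-Process Model of
    Sleep Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-driven simulation and analysis tools for the classical
    two-process model of sleep-wake regulation, in which an exponentially
    saturating homeostatic sleep pressure switches state at upper and lower
    thresholds modulated by a sinusoidal circadian rhythm.  Provides the
    closed-form natural-period formulas of the unforced relaxation
    oscillator, an exact (closed-form, no numerical ODE integration)
    hybrid simulator, circle-map and rotation-number machinery for
    classifying entrainment (n sleeps per m circadian periods), Arnold
    tongue parameter scans and Devil's staircase sweeps, raster-plot
    utilities, JSON parameter configuration and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
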