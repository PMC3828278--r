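Package: kingsa
Title: Global Sensitivity Analysis of Kinetic ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sampling-based and optimisation-based global sensitivity
    analysis for kinetic models of biochemical reaction networks. Models
    are read from SBML or built programmatically; outputs of interest are
    steady-state concentrations, steady-state fluxes, or oscillation
    periods. Scaled (dimensionless) sensitivity coefficients and metabolic
    control analysis (MCA) control coefficients are computed by relative
    finite differences, sampled over fractional parameter hypercubes by
    Monte Carlo, and bounded by particle swarm optimisation. Sensitivity
    distributions are characterised (unit-area histograms, peak location
    and height, Shapiro-Wilk normality), and a pattern-of-control
    robustness measure reports the parameter-variation level at which
    multiple control patterns emerge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
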