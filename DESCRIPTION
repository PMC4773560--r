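Package: adrenosim
Title: Kinetic Modelling of Adrenal Steroidogenesis in NCI-H295R Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward simulation and inverse analysis of a two-compartment
    kinetic model of adrenal steroidogenesis in the NCI-H295R
    adrenocortical cell line. The model couples cholesterol uptake,
    esterification and StAR-mediated mitochondrial localization to the
    C21-steroid biosynthesis pathway (17 enzymatic reactions, 9 enzymes)
    under competing-substrate rapid-equilibrium kinetics, with passive
    steroid diffusion between cells and culture medium and exponential
    cell growth. Provides an adaptive fourth-order Runge-Kutta
    integrator, calibration to steroid time courses by normalized least
    squares with Levenberg-Marquardt, mechanism-of-action estimation
    from 12-steroid fold-change profiles by a real-coded genetic
    algorithm (REX crossover, JGG generation alternation) hybridized
    with local search, dynamic sensitivity analysis, two-dimensional
    enzyme-activity phenotype scanning, and a synthetic-data generator
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
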