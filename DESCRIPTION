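Package: smfretsim
Title: Simulation and Analysis of Freely Diffusing Single-Molecule FRET
    Experiments with Conformational Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates photon timestamp data for freely diffusing
    single-molecule Foerster resonance energy transfer (smFRET)
    experiments in which the dye-dye distance of each molecule evolves by
    overdamped Langevin dynamics on a prescribed one-dimensional
    free-energy landscape, by exponential-residence state switching, or
    along an externally supplied (e.g. MD-derived) distance trajectory.
    Molecules additionally undergo three-dimensional Brownian diffusion
    through a Gaussian confocal point spread function and emit donor and
    acceptor photons as a Poisson process with background. The package
    also implements the matching analysis stack: millisecond binning and
    thresholding of apparent efficiencies, Gaussian and skew-Gaussian
    mixture models fitted by expectation-maximization, sliding-window
    burst search and selection, burst variance analysis, and a
    multi-sequence two-state Gaussian hidden Markov model, together with
    analytic Boltzmann densities and Berezhkovskii-Szabo interconversion
    kinetics for the prescribed landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    ggplot2,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
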