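Package: msmdesign
Title: Markov State Models, Designability Scoring and Relaxation-Dispersion
    Fitting for Conformational Landscape Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising and redesigning millisecond-timescale
    conformational landscapes of loop-exchanging proteins. Provides a
    synthetic kinetic-landscape generator (five-macrostate loop-exchange
    models with state-conditioned hydrogen-bond, chemical-shift and feature
    emissions), reversible Markov state model estimation with spectral
    (PCCA-style) coarse-graining, mean first passage times and trajectory
    bootstrap intervals, hydrogen-bond based designability ranking of
    candidate mutations, forward prediction of NMR observables (chemical
    shift perturbations, two-state exchange mapping, exchange broadening,
    heteronuclear NOE), and simulation plus global two-state fitting of
    CPMG and R1rho relaxation-dispersion data via the Carver-Richards
    equation cross-checked against a numerical Bloch-McConnell propagator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
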