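Package: burstkin
Title: Single-Channel Burst Kinetics and Thermodynamic Mutant-Cycle Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for equilibrium gating analysis of single ion channels that
    open in bursts, built around linear three-state aggregated Markov models
    (one open state, a fast "flickery" and a slow "interburst" closed state).
    Provides exact stochastic (Gillespie) simulation of gating trajectories,
    rendering of noisy low-pass-filtered current traces, half-amplitude
    threshold idealization with a fixed dead time, maximum-likelihood
    estimation of microscopic transition rate constants from dwell-time
    sequences with exact missed-event (dead-time) correction, closed-form
    descriptive burst parameters, single-exponential relaxation fitting of
    macroscopic ligand-removal decays, and thermodynamic double-mutant-cycle
    analysis of state-dependent interaction free energies with second-order
    error propagation and free-enthalpy profile construction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
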