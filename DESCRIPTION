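Package: activenematic
Title: Transition to Turbulence in Unconfined Active Nematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and chaos diagnostics for a minimal hydrodynamic
    model of two-dimensional, incompressible, defect-free active nematics
    on a doubly periodic domain. Solves the Stokes flow slaved to the
    director angle spectrally (2/3 dealiasing) and integrates the
    director dynamics with a Peaceman-Rachford ADI scheme; provides the
    closed-form linear stability of the aligned state, finite-time
    Lyapunov exponents, stretching numbers and Lyapunov spectra via
    shadow trajectories with Gram-Schmidt renormalization, the
    chaotic-fraction order parameter, oscillation fits, enstrophy
    kymographs, and quasi-static activity-ramp, hysteresis and ensemble
    protocols for mapping the sequence of bifurcations to chaos.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    data.table,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: fftw3
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
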