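Package: kinesim
Title: Monte Carlo Simulation of Single-Kinesin Cargo Transport in Viscous Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of cargo transport by a single kinesin-1
    motor along a one-dimensional microtubule lattice. The cargo undergoes
    thermal diffusion and deterministic drift in a viscous medium while
    coupled to the stepping motor through a finite-stiffness tether with a
    rest length; the motor detaches with Bell-type, direction-asymmetric
    load-dependent kinetics. Includes a closed-form diffusion-free model of
    velocity and run length under self-consistent viscous load, estimation
    procedures for run length (exponential-CDF fit with bootstrap standard
    errors), velocity, load and displacement statistics, and a sweep driver
    with presets covering viscosity, cargo size, velocity, motor stiffness
    and detachment-profile variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
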