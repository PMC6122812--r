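Package: neurofield
Title: Multiscale Neural-Field Simulation on Periodic 2D Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates interacting neural populations described by neural field
    theory on periodic two-dimensional grids. Populations are coupled through
    synaptodendritic filtering (biexponential impulse response integrated with
    fourth-order Runge-Kutta), a sigmoidal or linearized firing response, and
    axonal propagation by a damped 2D wave equation (explicit central
    differences with Courant-condition checking), its spatially uniform
    harmonic limit, or the local interaction approximation, with arbitrary
    inter-population conduction delays served from ring-buffer histories.
    Models are declared in a plain-text configuration dialect and results are
    written as plain-text timeseries files. Includes stimulus generators
    (constant, sinusoidal, pulse-train, Gaussian white noise), Welch temporal
    and wavenumber-resolved spatial power spectra, and closed-form linearized
    transfer functions and power spectra used to validate simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
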