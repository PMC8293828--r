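Package: adhops
Title: Adaptive Hierarchy of Pure States Simulation of Exciton Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of Frenkel exciton transport in molecular
    aggregates coupled to overdamped (Drude-Lorentz) vibrational environments,
    using the hierarchy of pure states (HOPS) unraveling of non-Markovian
    quantum state diffusion. Provides the linear, non-linear and normalized
    non-linear HOPS equations of motion, a Markovian short-time correction for
    the bath correlation function, FFT-based generation of correlated complex
    Gaussian noise, and an adaptive variant (adHOPS) that rebuilds a reduced
    auxiliary and state basis at every time step under a user-selected bound
    on the time-derivative error, yielding size-invariant cost for large
    aggregates. Includes ensemble averaging to reduced density matrices with
    bootstrap errors, transport observables (mean-squared displacement,
    diffusion coefficients), and independent cross-check integrators
    (hierarchical equations of motion, closed-form pure dephasing, Lindblad).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    parallel
Config/testthat/edition: 3
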