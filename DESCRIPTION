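Package: wcpac
Title: Wilson-Cowan Circuit Dynamics and Theta-Gamma Phase-Amplitude Coupling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and dynamical analysis of the canonical two-population
    excitatory-inhibitory Wilson-Cowan firing-rate circuit. Provides a
    fixed-step Runge-Kutta integrator with constant or sinusoidal drive,
    nullcline and equilibrium analysis with Jacobian-based stability
    classification, Hopf-bifurcation root-finding that locates the bounded
    oscillation window in input space, two-parameter oscillatory region maps,
    and phase-amplitude coupling analysis of theta-driven gamma activity
    (regime prediction from drive excursions, burst-phase classification, and
    a normalized Kullback-Leibler modulation index).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
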