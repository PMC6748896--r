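Package: pulsefd
Title: Frequency-Domain Solver for One-Dimensional Arterial Pulse Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves one-dimensional pulse-wave propagation in networks of
    compliant, tapering vessels in the frequency domain. Periodic inlet
    waveforms are expanded in Fourier harmonics; each harmonic is propagated
    through piecewise-conic transmission matrices with Womersley-based
    viscous friction, and the network boundary equations (inlet, branching
    and merging junctions, Windkessel or non-reflecting outlets) are
    assembled automatically into one small linear system per harmonic.
    Weakly nonlinear effects (convective steepening, nonlinear wall
    compliance, total-pressure junction matching) are captured by
    second-order perturbation corrections computed by quadrature along each
    segment. Includes pressure-area constitutive laws with their
    nonlinearity coefficients, empirical pulse-wave-velocity relations, and
    runnable verification scenarios with analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
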