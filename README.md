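# pulsefd

Frequency-domain solver for one-dimensional pulse-wave propagation in
arterial networks.

## The problem

Pressure and flow waves travel through the arterial tree, reflecting at
bifurcations, tapers and the peripheral vasculature. The standard 1D model
couples mass conservation, momentum with a convection coefficient α and a
wall-friction coefficient γ, and a pressure–area wall law A(p):

    A_t + q_x = 0
    q_t + (α q²/A)_x + (A/ρ) p_x + 2πγν q/A = 0
    A = A(p)

Space–time schemes solve these PDEs by marching; they struggle to represent
the skin friction of pulsatile flow, which is frequency dependent (the
Womersley solution), and they make outlet boundary conditions awkward.
`pulsefd` instead works harmonic by harmonic. Since cardiac waveforms are
periodic, every field is expanded as `x(t) = Σ X_n exp(iω_n t)`,
`ω_n = 2πn/T`, and the PDEs reduce to one linear 2×2 ODE system per
harmonic along each vessel:

    dP/dx = −iωρφ² Q/A,     dQ/dx = −iω A P/(ρc²)

with the complex viscous factor `φ = sqrt(1 − i·2πνγ/(ωA))` carrying the
exact Womersley friction `γ(ω)` and the lossy wavenumber `k = ωφ/c`. A
tapering vessel is approximated by a chain of truncated cones, each with a
closed-form 2×2 transmission matrix; their product maps the inlet
amplitudes `(P̂, Q̂)` of a segment to any position. For each harmonic the
inlet condition, the junction conditions (pressure continuity and mass
conservation, including merging junctions) and the outlet impedances
(three-element Windkessel `Z = R₁ + R₂/(1 + iωR₂C)`, plain resistance, or
exact non-reflecting loads) assemble automatically into a 2Nₛ×2Nₛ complex
linear system — one small solve per harmonic, for any network topology.

Weak nonlinearity (convective steepening, nonlinear wall compliance δ₁,
total-pressure junction matching ρu²/2) is restored by a second-order
perturbation pass: quadratic source terms built from the linear solution
are integrated along each segment by variation of parameters with
trapezoidal quadrature, and the boundary systems are re-solved with
corrected right-hand sides. The corrections scale exactly with the square
of the inlet amplitude and reproduce the closed-form solution for a
single-harmonic wave in a uniform pipe.

Who this is for: researchers in computational hemodynamics who need fast,
accurate 1D network solutions — for parameter studies, waveform analysis,
or as a reference for space–time codes.

## Worked example

Propagate a narrow Gaussian flow pulse along a 10 m compliant pipe
(radius 1 cm, wave speed 6.17 m/s, blood viscosity 0.04 cm²/s, constant
γ = 11) with a non-reflecting outlet, and track the peak:

```r
library(pulsefd)

g <- gaussian_decay_experiment(gamma_mode = 11)
g$decay_coefficient   # 0.07081  (1/m)  fitted from the peak trajectory
g$theory_coefficient  # 0.07131  (1/m)  = pi*gamma*nu/(c0*A0)
g$arrival_time        # 1.6208   (s)    ~ 10 m / 6.17 m/s = 1.62 s
```

The fitted exponential decay of the pulse peak agrees with the analytic
high-frequency rate `πγν/(c₀A₀)` to better than 1%, and the peak reaches
the outlet after the expected transit time.

Building a network by hand and solving it:

```r
net <- fixture_network("pipe_cone_pipe", q_max = 1e-6)  # pipe-taper-pipe
sol <- solve_with_corrections(net, n_harmonics = 32)    # linear + 2nd order
wf  <- evaluate_waveform(sol, "pipe_in", x = 1,
                         times = seq(0, 1, length.out = 256))
head(wf)   # data.frame(time, p [Pa], q [m^3/s])
```

Networks can also be described as JSON documents (segments, junctions,
inlet waveform, outlet models, units) and driven from the shell:

```sh
inst/scripts/pulsefd solve net.json --sites aorta:0.0,aorta:mid --harmonics 32 --nonlinear
inst/scripts/pulsefd scenario gaussian-decay --out out/
```

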