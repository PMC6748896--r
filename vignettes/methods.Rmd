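---
title: "Frequency-domain pulse-wave modelling with pulsefd: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain pulse-wave modelling with pulsefd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsefd)
```

## The model

`pulsefd` solves the standard one-dimensional equations for pressure
`p(x,t)`, flow rate `q(x,t)` and lumen area `A(p)` in a compliant vessel,

\[
A_t + q_x = 0,\qquad
q_t + \Big(\alpha\frac{q^2}{A}\Big)_x + \frac{A}{\rho}p_x
  + 2\pi\gamma\nu\frac{q}{A} = 0,\qquad A = A(p),
\]

under three assumptions: the waveform is strictly periodic with period
$T$; departures from the equilibrium state $(p_0, A_0)$ are small enough
that a second-order perturbation expansion captures the nonlinearity; and
the wall responds elastically (no viscoelastic loss). Linearizing about
equilibrium and expanding all fields in harmonics
$x(t)=\sum_n X_n e^{i\omega_n t}$, $\omega_n = 2\pi n/T$, turns the PDEs
into an independent pair of ODEs per harmonic,

\[
P_x = -\,i\omega\rho\phi^2\,\frac{Q}{A},\qquad
Q_x = -\,i\omega\,\frac{A}{\rho c^2}\,P ,
\]

where $c$ is the local pulse wave velocity, $c^2 = A/(\rho\,dA/dp)$, and
$\phi=\sqrt{1-i\,2\pi\nu\gamma/(\omega A)}$ is the complex viscous factor.
The principal branch with $\operatorname{Im}\phi\le 0$ is enforced so the
forward wave $e^{-ikx}$, $k=\omega\phi/c$, decays downstream. The steady
component ($n=0$) is Poiseuille flow: constant $q$, pressure dropping as
$8\pi\mu\!\int\!dx/A^2$.

### Wall friction

The friction coefficient $\gamma$ is the dimensionless wall-shear factor
$-a\,u_r(a)/\bar u$. For steady flow it is 4; for oscillatory flow it
follows from the Womersley velocity profile
$u(r)\propto 1-J_0(\Lambda r/a)/J_0(\Lambda)$ with
$\Lambda = i^{3/2} w$, $w=a\sqrt{\omega/\nu}$:

\[
\gamma(\omega) = -\frac{\Lambda^2 r}{\Lambda - 2r},\qquad
r = \frac{J_1(\Lambda)}{J_0(\Lambda)} .
\]

The Bessel ratio is evaluated by a modified Lentz continued fraction,
which is stable at all Womersley numbers of interest (no cancellation,
unlike the power series beyond $w\approx 30$); the $\omega\to 0$ limit
returns 4 exactly and the small-$w$ expansion $4 + i w^2/6$ is used below
$w=10^{-3}$. The solver exposes three friction modes: `"womersley"`
(default; frequency- and radius-dependent), a constant user value (e.g.
4 or the empirical 11 for large arteries), and `"inviscid"`. The steady
component always uses $\gamma=4$ through the viscosity, regardless of
mode. A user-supplied function `gamma(a, omega, nu)` is also accepted, so
a flexible-wall variant can be plugged in without touching the solver.

### Wall laws and their nonlinearity coefficients

Five pressure–area relations are provided (constant stiffness, the
inverse-square-root law, the power law that generalizes both, the
logarithmic-diameter law, and the exponential law), all parameterized by
$(A_0, c_0, p_0)$. Their second-order behaviour enters the nonlinear
corrections only through the coefficients of the compliance expansion
$A'(p)/A'(p_0) = 1 + \delta_1\hat p + \delta_2\hat p^2 + \dots$,
$\hat p = \Delta p/(\rho c_0^2)$. In terms of the normalized derivatives
$g_k = (\rho c_0^2)^k A^{(k)}(p_0)/A_0$ the package uses

\[
\delta_1 = g_2,\qquad \delta_2 = g_3/2,\qquad \delta_3 = g_4/2 ,
\]

the normalization under which all published per-model values are
reproduced simultaneously (power law $\delta_1=(2-b)/2$,
$\delta_2=(b-1)(b-2)/4$; the inverse-square-root law $(3/2, 3/2, 15/4)$;
the exponential law $(-1, 1, -3)$); these are dimensionless, which fixes
the powers of $\rho c_0^2$ unambiguously. A high-order central-difference
route (`delta_coefficients_numeric`, 7-point stencils with one Richardson
step, default dimensionless step 0.02) serves as an independent check and
covers laws without closed forms; its agreement with the closed forms is
at the $10^{-7}$ level. The exponential law is printed for $A \ge A_0$
only; its closed-form inverse $A = A_0(1+\log(1+\hat p))$ is smooth and
monotone and is used on both sides of $A_0$ — an extension, not a claim
about the original model's intent.

## Discretization and the transmission-matrix method

Each segment of length $L$ is split into $N_e=\lceil L/h_b\rceil$ equal
elements (basic element length $h_b$, default 1 cm) with radii
interpolated between the printed inlet/outlet values — linearly in radius
by default, with linear-in-area and exponential options (linear-in-area
produces a convex, unrealistic profile and is kept only for
comparisons). Node wave speeds come from a constant, a per-node vector,
or one of three empirical PWV–radius fits (exponential, biexponential,
power-law; all stated in cm internally, SI at the interface).

Across one element the wavenumber, wave speed and viscous factor are
frozen at their endpoint means ($\bar k_i = \tfrac{\omega}{2}
(\phi_{i-1}/c_{i-1}+\phi_i/c_i)$, etc.) while the radius varies linearly,
which admits a closed-form $2\times2$ transmission matrix per element
with the taper parameter $\zeta_i = a_{x i}/(\bar k_i a_i)$; the segment
matrix is the ordered product. For a uniform segment the element matrix
is exact; for a cone with constant $c$ it is exact as well, so
discretization error comes only from the variation of $c(x)$ and
$\phi(x)$ — observed convergence on a strongly tapering carotid segment
is second order in $h$, with relative error $\sim10^{-4}$ at $h=5$ mm.
The reference for these checks is `ode_transmission`, an adaptive
complex-ODE integration (via `deSolve::zvode`) of the two canonical
initial-value problems at tolerance $10^{-10}$; internally it integrates
the scaled state $(P, Z_0 Q)$ so both components are $O(1)$ and the
absolute tolerance is meaningful across the ~$10^9$ dynamic range between
pressure and flow amplitudes.

## The network solve

With $N_s$ segments the unknowns per harmonic are the inlet amplitudes
$(\hat P_s, \hat Q_s)$; inlet, junction and outlet conditions supply
exactly $2N_s$ equations. Inlet waveforms may be prescribed as full
values or as forward-travelling waves (the latter eliminates the
backward amplitude through the first element's characteristic impedance
and taper parameter). Junctions accept any number of parents and
daughters: pressure-continuity rows tie each endpoint to the first
parent's outlet and one row conserves mass. Outlets are three-element
Windkessel impedances, plain resistances, or non-reflecting loads
$Z = \tilde Z/(1-i\zeta)$ — the exact forward-wave impedance of a conic
end, re-derived from the travelling-wave split rather than taken from
the printed composite expression, and verified by the absorbed-energy
property (reflected energy below $10^{-6}$ of incident in the tests).

Forward-wave inlet kinds fall back to the full-value equation at $n=0$:
the mean flow has no forward/backward decomposition. The steady closure
is either the outlet resistances or Murray's law
($q_d \propto a_d^\xi$, default $\xi = 3$, with 2.76 accepted for
arterial flow) plus a prescribed inlet mean pressure; Murray closure is
restricted to tree topologies (a merging junction has no defined split).
Before solving, pressure columns are scaled by $\rho c^2$ and flow
columns by $A c$, so the dense complex solve operates on $O(1)$ entries;
systems are small ($2N_s$) and solved directly. With zero viscosity and
zero outlet resistance the steady flow split of a branching network is
genuinely indeterminate — the solver reports the singular system rather
than picking a split.

## Second-order corrections

The quadratic source terms are built from the linear solution segment by
segment: time-domain fields and their derivatives are reconstructed
spectrally ($p_t$ from $i\omega_n P_n$; $p_x$ and $q_x$ through the
propagation equations, which avoids numerical differentiation), products
are formed on a time grid of $4N+4$ points — enough to represent the
full $2N$-band of quadratic products without aliasing — and transformed
back by FFT. Row 1 is
$-(\rho\alpha/A^2)(2qq_x - q^2A_x/A) - \Delta p\,p_x/(\rho c^2)$; row 2
is $-\delta_1 (A/\rho^2c^4)\,\Delta p\,p_t$. The viscosity–nonlinearity
cross term is small and excluded by default (a flag restores it). The
convection coefficient defaults to $\alpha = 4/3$, the parabolic-profile
value; $\delta_1$ comes from each segment's wall law (0.5, the
constant-stiffness value, when none is attached).

The inhomogeneous per-harmonic ODEs are integrated along each segment by
variation of parameters with zero initial conditions at the segment
inlet: cumulative trapezoidal quadrature of the source determinants on
the element nodes, composed with the node transmission matrices. The
textbook form of this quadrature assumes $\det T = 1$; the implementation
divides by the actual determinant, which is identical for the exact flow
and guards the piecewise-conic approximation. At junctions the
total-pressure matching contributes velocity-head spectra
$\tfrac{\rho}{2}(U_s^2 - U_d^2)_n$ with $u = q^{(1)}/A$; the sign of
these terms in the corrected rows follows from substituting the matching
relation directly (the printed corrected system carries the opposite
sign on that one term — an inconsistency resolved in favour of the
derivation, and covered by the matched-velocity cancellation tests). The
second pass re-solves the same boundary matrices with corrected
right-hand sides; only the order-$\varepsilon^2$ correction is computed,
no higher iterations.

### The closed-form oracle

For a single-harmonic forward wave
$\hat p^{(1)}=\hat q^{(1)}=\varepsilon\,[(1-\xi)+\xi\cos(\omega t-kx)]$
in a uniform inviscid pipe, the corrections have the exact form

\[
\hat p^{(2)} = B_1^+\sin(\omega t-kx)\,kx + B_1^-\sin\omega t\sin kx
 + B_2^+\sin 2(\omega t-kx)\,2kx + B_2^-\sin 2\omega t\sin 2kx,
\]

with $B_1^\pm=-\varepsilon^2\xi(1-\xi)(2\alpha+1\mp\delta_1)/2$ and
$B_2^\pm=-\varepsilon^2\xi^2(2\alpha+1\mp\delta_1)/8$ (flip the signs of
$B^-$ for $\hat q^{(2)}$). This was re-derived by characteristics rather
than copied: the published wave convention pairs the $\xi^2$
double-frequency coefficients with a wave whose oscillating amplitude is
$(1-\xi)$, which cannot both hold (a pure oscillation would then carry no
double-frequency correction); with $\xi$ as the *oscillating* fraction
the coefficient set is exactly consistent, and at the validation point
$\xi=1/2$ the two readings coincide. The $kx$-proportional terms are the
secular components responsible for wavefront steepening; their slope
$\propto 2\alpha+1-\delta_1$ is verified by direct fit in the tests.

`quadrature_accuracy_study()` imposes this wave on a discretized 10 m
pipe ($a_0=1$ cm, $c_0=6.17$ m/s) and measures
$\max_{x,t}|{\rm numeric}-{\rm analytic}|/\max_{x,t}|{\rm analytic}|$
separately for the pressure and flow corrections. The wave period is
taken as 1 s — the heartbeat scale, and the period of the tapering-vessel
scenario; the study that this reproduces does not state its period or
norm. At the reference element length $h=2$ cm the measured error is
$\approx 2\times10^{-3}\,\%$, i.e. the trapezoidal quadrature at this
mesh is more accurate than the ~0.06 % quoted for the original
experiment under any heartbeat-scale period.

## Verification scenarios and what they do (and do not) show

The validation fixtures are synthetic networks that emulate the study
conditions of published verification experiments, not patient data:

* **Gaussian decay** (`gaussian_decay_experiment`): 10 m pipe, radius
  1 cm, $c_0 = 6.17$ m/s, $\rho=1.04$ g/cm³, $\nu=0.04$ cm²/s, period
  4 s (long enough that periodic images of the pulse do not overlap the
  10/6.17 = 1.62 s transit), inlet flow pulse
  $\exp\{-(t-0.05)^2/0.01^2\}$ cm³/s, non-reflecting outlet, 512
  harmonics. With constant $\gamma=11$ the fitted peak decay
  (least squares on the log-peak over $x\in[2,9]$ m, quadratic peak
  interpolation, away from inlet transients) reproduces the analytic
  high-frequency rate $\pi\gamma\nu/(c_0A_0)=0.0713\ \mathrm{m^{-1}}$ to
  better than 1%; Womersley-mode friction decays this very narrow pulse
  markedly faster, as its high harmonics see $\gamma>11$.
* **Spectral content**: the same pulse expanded over a 1 s period
  crosses 95% of its squared-amplitude energy (steady term excluded) at
  harmonic index 31 — i.e. it needs the 32 Fourier components
  $n=0..31$. The crossing is robust (cumulative fraction 0.9433 at 30,
  0.95102 at 31) but close to the threshold, which is why the energy
  convention is fixed once: squared amplitudes, positive harmonics, the
  1 s heartbeat-scale period. `energy_count()` returns the index; the
  component count is that plus one.
* **Tapering segment** (`pipe_cone_pipe`): 1 m pipe — 9.4 cm cone
  (diameters 6.75→3.5 mm, biexponential PWV law) — 1 m pipe, bell-shaped
  inlet flow of duration $T/4$ on $T=1$ s, non-reflecting outlet. The
  long first pipe separates the forward and cone-reflected pulses in
  time at the midpoint site. Used for the $\varepsilon^2$-scaling and
  reference-subtraction checks of the corrections.
* **Branching/merging fixtures**: symmetric 1→2 bifurcation and a 2→1
  merging junction, for the mass/pressure-continuity residual tests.

Passing these shows the solver reproduces the linear wave physics and
the leading nonlinear correction under idealized conditions. It does not
show fidelity to real arterial data: the fixtures have no viscoelastic
wall damping, no side-branch leakage, no measured geometries or
waveforms, and the periodicity assumption hides beat-to-beat
variability.

## Numerical choices, degenerate inputs, problem sizes

* Fourier convention: two-sided amplitudes with $X_{-n}=\bar X_n$, only
  $n\ge0$ stored; `decompose` requires $\ge 2N+2$ uniform samples over
  exactly one period and rejects non-uniform grids; the default $N$
  captures 99.99% of the oscillatory energy, capped at half the sample
  count.
* Units: SI everywhere inside; mmHg and CGS conversions
  (1 mmHg = 133.322 Pa) only at the I/O boundary. Network files declare
  `units: "SI"` or `"CGS"`.
* Branch cuts: $\operatorname{Im}\phi\le0$ and hence
  $\operatorname{Im}k\le0$ are enforced by sign flip after the principal
  square root.
* Zero-frequency requests to the harmonic machinery are rejected rather
  than regularized; the steady path handles $n=0$.
* A segment much shorter than its neighbours behaves as an identity
  coupler (verified down to $10^{-7}$ m); zero-length segments are not
  representable.
* Default problem sizes keep every scenario at interactive scale: 512
  harmonics × 20 elements for the Gaussian run (~7 s), 500 elements × 3
  harmonics for the quadrature study (<1 s), 2×–3×-segment networks at
  12–48 harmonics in the tests. These sizes were chosen so the full
  suite exercises every code path in well under a minute.

## Known limitations

Viscoelastic wall loss, lateral mass loss into small branches, junction
pressure-loss models with angle dependence, time-varying $\alpha(t)$ and
$\gamma(t)$, and perturbation orders beyond the second are out of scope.
Murray's steady closure requires a tree. The frequency-domain method is
inherently periodic: transients and single pulses are handled by
embedding them in a long period, which costs harmonics proportionally to
the period-to-pulse-width ratio.
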