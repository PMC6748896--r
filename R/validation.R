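# Analytic oracles and runnable verification scenarios.

#' Single-harmonic linear wave in a uniform pipe
#'
#' The manufactured forward-travelling linear field
#' `p^ = q^ = eps ((1 - xi) + xi cos(w t - k x))`, `k = w / c_0`, used to
#' validate the second-order quadrature against the closed-form
#' correction. `xi` is the oscillating fraction (`xi = 0` pure steady,
#' `xi = 1` pure oscillation); `eps` is the dimensionless amplitude
#' `Dp_max / (rho c_0^2)`.
#'
#' @param eps Amplitude factor.
#' @param xi Mix parameter in `[0, 1]`.
#' @param omega Angular frequency (rad/s).
#' @param a_0 Pipe radius (m).
#' @param c_0 Wave speed (m/s).
#' @param rho Fluid density (kg/m^3).
#' @return List describing the wave (class `uniform_pipe_wave`).
#' @export
uniform_pipe_wave <- function(eps, xi, omega, a_0, c_0, rho = 1040) {
  stopifnot(eps > 0, xi >= 0, xi <= 1, omega > 0)
  structure(list(eps = eps, xi = xi, omega = omega, a_0 = a_0, c_0 = c_0,
                 rho = rho, k = omega / c_0, area = pi * a_0^2),
            class = "uniform_pipe_wave")
}

#' Closed-form second-order correction for the uniform-pipe wave
#'
#' Exact dimensionless corrections
#' `p^(2) = B1+ sin(wt - kx) kx + B1- sin(wt) sin(kx)
#'        + B2+ sin(2wt - 2kx) 2kx + B2- sin(2wt) sin(2kx)` and the same
#' for `q^(2)` with the signs of `B1-`, `B2-` flipped, where
#' `B1± = -eps^2 xi (1 - xi) (2 alpha + 1 -+ delta_1)/2` and
#' `B2± = -eps^2 xi^2 (2 alpha + 1 -+ delta_1)/8`,
#' for an inviscid uniform pipe with zero corrections at the inlet. The
#' terms growing linearly in `kx` are the secular (front-steepening)
#' components.
#'
#' @param wave A [uniform_pipe_wave()].
#' @param x Position(s) (m).
#' @param t Time(s) (s); `x` and `t` are recycled against each other.
#' @param alpha Convection coefficient.
#' @param delta1 Wall nonlinearity coefficient.
#' @return List of numeric `p2_hat`, `q2_hat` (dimensionless; multiply by
#'   `rho c_0^2` and `A_0 c_0` for physical units).
#' @export
analytic_nonlinear_correction <- function(wave, x, t, alpha = 4 / 3,
                                          delta1 = 0.5) {
  cf <- analytic_correction_coefficients(wave$eps, wave$xi, alpha, delta1)
  k <- wave$k; w <- wave$omega
  s1p <- sin(w * t - k * x) * (k * x)
  s1m <- sin(w * t) * sin(k * x)
  s2p <- sin(2 * w * t - 2 * k * x) * (2 * k * x)
  s2m <- sin(2 * w * t) * sin(2 * k * x)
  list(p2_hat = cf$B1p * s1p + cf$B1m * s1m + cf$B2p * s2p + cf$B2m * s2m,
       q2_hat = cf$B1p * s1p - cf$B1m * s1m + cf$B2p * s2p - cf$B2m * s2m)
}

#' @rdname analytic_nonlinear_correction
#' @param eps,xi Wave parameters (see [uniform_pipe_wave()]).
#' @export
analytic_correction_coefficients <- function(eps, xi, alpha = 4 / 3,
                                             delta1 = 0.5) {
  list(B1p = -eps^2 * xi * (1 - xi) * (2 * alpha + 1 - delta1) / 2,
       B1m = -eps^2 * xi * (1 - xi) * (2 * alpha + 1 + delta1) / 2,
       B2p = -eps^2 * xi^2 * (2 * alpha + 1 - delta1) / 8,
       B2m = -eps^2 * xi^2 * (2 * alpha + 1 + delta1) / 8)
}

#' Quadrature accuracy against the closed-form correction
#'
#' Reproduces the quadrature-accuracy study: the manufactured wave of
#' [uniform_pipe_wave()] is imposed as the linear field on a discretized
#' uniform inviscid pipe, its second-order correction is computed by
#' [nonlinear_source()] + [correction_quadrature()], and the result is
#' compared with [analytic_nonlinear_correction()] on the element nodes
#' over one period. The error is
#' `max_{x,t} |numeric - analytic| / max_{x,t} |analytic|`, reported
#' separately for the pressure and flow corrections.
#'
#' @param pipe_length Pipe length (m).
#' @param a_0,c_0,rho Pipe and fluid parameters.
#' @param period Wave period (s); the wave is the first harmonic.
#' @param eps,xi Wave amplitude and mix parameters.
#' @param h Element length (m).
#' @param alpha,delta1 Nonlinearity coefficients.
#' @param n_times Time samples per period for the comparison.
#' @return List with `rel_error_p`, `rel_error_q` (fractions), the node
#'   grid and both correction fields.
#' @export
quadrature_accuracy_study <- function(pipe_length = 10, a_0 = 0.01,
                                      c_0 = 6.17, rho = 1040, period = 1,
                                      eps = 0.05, xi = 0.5, h = 0.02,
                                      alpha = 4 / 3, delta1 = 0.5,
                                      n_times = 64L) {
  wave <- uniform_pipe_wave(eps, xi, 2 * pi / period, a_0, c_0, rho)
  seg <- vessel_segment("pipe", pipe_length, a_0, element_length = h,
                        pwv = c_0)
  props <- fluid_properties(rho, nu = 0)
  nmax <- 2L
  nn <- seg$n_elements + 1L
  # manufactured linear amplitudes on the nodes (forward wave, Eq-style)
  P <- matrix(0i, nmax + 1L, nn)
  Q <- matrix(0i, nmax + 1L, nn)
  rc2 <- rho * c_0^2
  P[1L, ] <- rc2 * eps * (1 - xi)
  P[2L, ] <- rc2 * eps * xi / 2 * exp(-1i * wave$k * seg$x)
  Q[1L, ] <- wave$area * c_0 * eps * (1 - xi)
  Q[2L, ] <- wave$area * c_0 * eps * xi / 2 * exp(-1i * wave$k * seg$x)
  phi <- matrix(1 + 0i, nmax, nn)
  src <- nonlinear_source_core(seg, P, Q, period, props, phi,
                               alpha = alpha, delta1 = delta1, p_ref = 0)
  sol <- manufactured_solution(seg, props, period, nmax)
  cf <- correction_quadrature(sol, "pipe", src)
  t_k <- seq(0, period, length.out = n_times + 1L)[-(n_times + 1L)]
  # reconstruct_matrix is time x node, column-major vectorization is
  # time-fastest; build the comparison grid in the same order
  num_p <- as.vector(reconstruct_matrix(cf$P2, period, n_times))
  num_q <- as.vector(reconstruct_matrix(cf$Q2, period, n_times))
  grid <- expand.grid(t = t_k, x = seg$x)
  ana <- analytic_nonlinear_correction(wave, grid$x, grid$t, alpha, delta1)
  p2_ana <- ana$p2_hat * rc2
  q2_ana <- ana$q2_hat * wave$area * c_0
  list(rel_error_p = max(abs(num_p - p2_ana)) / max(abs(p2_ana)),
       rel_error_q = max(abs(num_q - q2_ana)) / max(abs(q2_ana)),
       x = seg$x, P2 = cf$P2, Q2 = cf$Q2, wave = wave)
}

# minimal pulse_solution carrying the per-harmonic node matrices of one
# segment, for driving correction_quadrature() with a manufactured field
manufactured_solution <- function(seg, props, period, nmax) {
  net <- network_model(
    segments = list(seg),
    inlet = list(segment = seg$id, kind = "flow_forward",
                 spectrum = harmonic_spectrum(rep(0i, nmax + 1L), period,
                                              "flow")),
    outlets = stats::setNames(list(list(model = "non_reflecting")), seg$id),
    fluid = props, gamma_mode = "inviscid")
  sh <- lapply(seq_len(nmax), function(n)
    stats::setNames(list(segment_transmission(seg, 2 * pi * n / period,
                                              props, "inviscid")), seg$id))
  structure(list(network = net, period = period, n_max = nmax,
                 harmonics = c(list(NULL), sh)),
            class = "pulse_solution")
}

#' Gaussian-pulse viscous decay experiment
#'
#' Propagates a narrow Gaussian flow pulse
#' `q_in(t) = q_peak exp(-(t - t_c)^2 / tau^2)` along a long uniform pipe
#' with a non-reflecting outlet, tracks the pulse peak versus distance,
#' and fits the exponential decay coefficient. For harmonics well above
#' the viscous frequency `w_nu = 2 pi gamma nu / A_0` the theoretical
#' decay rate is `pi gamma nu / (c_0 A_0)` per metre.
#'
#' @param gamma_mode Friction model: a number (e.g. 11) or `"womersley"`.
#' @param pipe_length,a_0,c_0 Pipe geometry (m, m, m/s).
#' @param rho,nu Fluid properties (kg/m^3, m^2/s).
#' @param period Signal period (s); must comfortably exceed the transit
#'   time so that periodic images do not overlap.
#' @param q_peak,t_c,tau Inlet pulse parameters (m^3/s, s, s).
#' @param n_harmonics Harmonics retained.
#' @param sites Observation positions (m).
#' @param fit_range Positions used for the log-linear decay fit (m).
#' @return List with the peak table (`x`, `peak`, `t_peak`), fitted
#'   `decay_coefficient` (1/m), `theory_coefficient`, and
#'   `arrival_time` = outlet peak time minus `t_c` (s).
#' @export
gaussian_decay_experiment <- function(gamma_mode = 11, pipe_length = 10,
                                      a_0 = 0.01, c_0 = 6.17, rho = 1040,
                                      nu = 4e-6, period = 4,
                                      q_peak = 1e-6, t_c = 0.05, tau = 0.01,
                                      n_harmonics = 512L,
                                      sites = seq(0, 10, by = 0.5),
                                      fit_range = c(2, 9)) {
  net <- gaussian_pipe_network(gamma_mode, pipe_length, a_0, c_0, rho, nu,
                               period, q_peak, t_c, tau, n_harmonics)
  sol <- solve_linear(net, n_harmonics)
  m <- 8192L
  t_k <- (0:(m - 1L)) * period / m
  peaks <- vapply(sites, function(xs) {
    hf <- harmonic_field(sol, "pipe", xs)
    qt <- fourier_reconstruct(hf$Q, t_k, period)
    pk <- refine_peak(t_k, qt)
    c(pk$value, pk$time)
  }, numeric(2L))
  peak <- peaks[1L, ]; t_peak <- peaks[2L, ]
  in_fit <- sites >= fit_range[1L] & sites <= fit_range[2L]
  decay <- if (sum(in_fit) >= 2L) {
    fit <- stats::lm(log(peak[in_fit]) ~ sites[in_fit])
    -unname(stats::coef(fit)[2L])
  } else NA_real_
  gamma_eff <- if (is.numeric(gamma_mode)) gamma_mode else NA_real_
  list(x = sites, peak = peak, t_peak = t_peak,
       decay_coefficient = decay,
       theory_coefficient = if (is.na(gamma_eff)) NA_real_ else
         pi * gamma_eff * nu / (c_0 * pi * a_0^2),
       arrival_time = t_peak[length(sites)] - t_c,
       solution = sol)
}

gaussian_pipe_network <- function(gamma_mode, pipe_length, a_0, c_0, rho, nu,
                                  period, q_peak, t_c, tau, n_harmonics) {
  m <- max(4L * n_harmonics, 2048L)
  t_k <- (0:(m - 1L)) * period / m
  q_in <- q_peak * exp(-(t_k - t_c)^2 / tau^2)
  seg <- vessel_segment("pipe", pipe_length, a_0, element_length = 0.5,
                        pwv = c_0)
  network_model(
    segments = list(seg),
    inlet = list(segment = "pipe", kind = "flow_forward",
                 spectrum = fourier_decompose(q_in, period,
                                              n_max = n_harmonics,
                                              quantity = "flow")),
    outlets = list(pipe = list(model = "non_reflecting")),
    fluid = fluid_properties(rho, nu),
    gamma_mode = gamma_mode)
}

# quadratic interpolation of the discrete maximum
refine_peak <- function(t, y) {
  i <- which.max(y)
  n <- length(y)
  im <- if (i == 1L) n else i - 1L
  ip <- if (i == n) 1L else i + 1L
  dt <- t[2L] - t[1L]
  den <- y[im] - 2 * y[i] + y[ip]
  off <- if (den == 0) 0 else 0.5 * (y[im] - y[ip]) / den
  list(time = t[i] + off * dt,
       value = y[i] - 0.25 * (y[im] - y[ip]) * off)
}

#' Reference-subtraction estimate of the nonlinear correction
#'
#' Extracts the second-order correction from two runs of the full solver
#' at different inlet amplitudes: a working amplitude `q_max` and a small
#' reference `q_max_ref`. With `Dp = p - mean(p)`,
#' `p2 = Dp - Dp_ref (q_max / q_max_ref)` and
#' `q2 = q - q_ref (q_max / q_max_ref)`.
#'
#' @param run Waveform `data.frame(time, p, q)` at the working amplitude.
#' @param run_ref Same site and time grid at the reference amplitude.
#' @param q_max,q_max_ref The two inlet peak amplitudes.
#' @return `data.frame(time, p2, q2)`.
#' @export
reference_subtraction <- function(run, run_ref, q_max, q_max_ref) {
  if (nrow(run) != nrow(run_ref) ||
      max(abs(run$time - run_ref$time)) > 1e-12 * max(abs(run$time), 1))
    stop("runs must share one time grid")
  s <- q_max / q_max_ref
  dp <- run$p - mean(run$p)
  dp_ref <- run_ref$p - mean(run_ref$p)
  data.frame(time = run$time,
             p2 = dp - dp_ref * s,
             q2 = run$q - run_ref$q * s)
}

#' Catalog of verification network fixtures
#'
#' Ready-made [network_model()] instances used across the validation
#' scenarios and tests:
#'
#' * `single_pipe`: the 10 m, 1 cm-radius uniform pipe of the
#'   Gaussian-decay experiment (`c_0 = 6.17` m/s, `T = 4` s).
#' * `carotid_cone`: a 9.4 cm cone tapering from 6.75 to 3.5 mm diameter
#'   with the biexponential PWV-radius law, between matched pipes.
#' * `pipe_cone_pipe`: 1 m pipe, the carotid cone, 1 m pipe; bell-shaped
#'   inlet flow of duration `T/4` on a 1 s period; non-reflecting outlet.
#' * `bifurcation`: symmetric junction of one parent into two daughters.
#' * `merging`: two parents joining into one daughter.
#'
#' @param name Fixture name.
#' @param q_max Inlet peak flow for `pipe_cone_pipe` (m^3/s).
#' @param gamma_mode Friction model override.
#' @param n_harmonics Harmonic count used to sample inlet waveforms.
#' @return A [network_model()].
#' @export
fixture_network <- function(name = c("single_pipe", "carotid_cone",
                                     "pipe_cone_pipe", "bifurcation",
                                     "merging"),
                            q_max = 0.1e-6, gamma_mode = 4,
                            n_harmonics = 64L) {
  name <- match.arg(name)
  props <- fluid_properties(1040, 4e-6)
  a1 <- 6.75e-3 / 2; a2 <- 3.5e-3 / 2
  bell <- function(period, m = max(4L * n_harmonics, 512L)) {
    t_k <- (0:(m - 1L)) * period / m
    delta <- period / 4
    q <- ifelse(t_k < delta,
                q_max * 0.5 * (1 + cos((2 * pi / delta) * (t_k - delta / 2))),
                0)
    fourier_decompose(q, period, n_max = n_harmonics, quantity = "flow")
  }
  switch(name,
    single_pipe = gaussian_pipe_network(11, 10, 0.01, 6.17, 1040, 4e-6, 4,
                                        1e-6, 0.05, 0.01, n_harmonics),
    carotid_cone = {
      cone <- vessel_segment("cone", 0.094, a1, a2, element_length = 0.005,
                             pwv_law = "blanco_biexp")
      network_model(
        segments = list(cone),
        inlet = list(segment = "cone", kind = "flow_forward",
                     spectrum = bell(1)),
        outlets = list(cone = list(model = "non_reflecting")),
        fluid = props, gamma_mode = gamma_mode)
    },
    pipe_cone_pipe = {
      segs <- list(
        vessel_segment("pipe_in", 1, a1, element_length = 0.02,
                       pwv_law = "blanco_biexp"),
        vessel_segment("cone", 0.094, a1, a2, element_length = 0.005,
                       pwv_law = "blanco_biexp"),
        vessel_segment("pipe_out", 1, a2, element_length = 0.02,
                       pwv_law = "blanco_biexp"))
      network_model(
        segments = segs,
        junctions = list(list(parents = "pipe_in", daughters = "cone"),
                         list(parents = "cone", daughters = "pipe_out")),
        inlet = list(segment = "pipe_in", kind = "flow_forward",
                     spectrum = bell(1)),
        outlets = list(pipe_out = list(model = "non_reflecting")),
        fluid = props, gamma_mode = gamma_mode)
    },
    bifurcation = {
      segs <- list(
        vessel_segment("parent", 0.2, 0.005, element_length = 0.02, pwv = 5),
        vessel_segment("d1", 0.15, 0.0035, element_length = 0.02, pwv = 5),
        vessel_segment("d2", 0.15, 0.0035, element_length = 0.02, pwv = 5))
      network_model(
        segments = segs,
        junctions = list(list(parents = "parent",
                              daughters = c("d1", "d2"))),
        inlet = list(segment = "parent", kind = "flow_forward",
                     spectrum = bell(1)),
        outlets = list(d1 = list(model = "non_reflecting"),
                       d2 = list(model = "non_reflecting")),
        fluid = props, gamma_mode = gamma_mode)
    },
    merging = {
      segs <- list(
        vessel_segment("inlet_trunk", 0.1, 0.005, element_length = 0.02,
                       pwv = 5),
        vessel_segment("v1", 0.15, 0.0035, element_length = 0.02, pwv = 5),
        vessel_segment("v2", 0.15, 0.0035, element_length = 0.02, pwv = 5),
        vessel_segment("basilar", 0.1, 0.004, element_length = 0.02,
                       pwv = 5))
      network_model(
        segments = segs,
        junctions = list(
          list(parents = "inlet_trunk", daughters = c("v1", "v2")),
          list(parents = c("v1", "v2"), daughters = "basilar")),
        inlet = list(segment = "inlet_trunk", kind = "flow_forward",
                     spectrum = bell(1)),
        outlets = list(basilar = list(model = "non_reflecting")),
        fluid = props, gamma_mode = gamma_mode)
    })
}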