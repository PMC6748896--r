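# Second-order perturbation corrections: quadratic source terms built from
# the linear harmonic solution, quadrature integration along each segment,
# and the corrected network pass.

# Node amplitudes P_n(x_j), Q_n(x_j) of the linear solution on one segment.
node_amplitudes <- function(solution, segment) {
  seg <- solution$network$segments[[segment]]
  nn <- seg$n_elements + 1L
  nmax <- solution$n_max
  P <- matrix(0i, nmax + 1L, nn)
  Q <- matrix(0i, nmax + 1L, nn)
  mu <- solution$network$fluid$mu
  cumint <- cumtrapz(seg$x, 1 / (pi * seg$a^2)^2)
  P[1L, ] <- solution$P_hat[1L, segment] -
    8 * pi * mu * solution$Q_hat[1L, segment] * cumint
  Q[1L, ] <- solution$Q_hat[1L, segment]
  for (n in seq_len(nmax)) {
    Tn <- solution$harmonics[[n + 1L]][[segment]]$T_nodes
    v <- c(solution$P_hat[n + 1L, segment], solution$Q_hat[n + 1L, segment])
    for (j in seq_len(nn)) {
      w <- Tn[, , j] %*% v
      P[n + 1L, j] <- w[1L]; Q[n + 1L, j] <- w[2L]
    }
  }
  list(P = P, Q = Q)
}

# dA/dx at the segment nodes, from the radius interpolation in force.
segment_dAdx <- function(seg) {
  a_in <- seg$a[1L]; a_out <- seg$a[seg$n_elements + 1L]; L <- seg$length
  dadx <- switch(seg$interpolation,
    radius = rep((a_out - a_in) / L, length(seg$x)),
    area = (a_out^2 - a_in^2) / (2 * L * seg$a),
    exponential = seg$a * log(a_out / a_in) / L)
  2 * pi * seg$a * dadx
}

# reconstruct a (N+1) x n_nodes amplitude matrix on an M-point time grid:
# rows of the result are time, columns nodes
reconstruct_matrix <- function(X, period, M) {
  nmax <- nrow(X) - 1L
  t_k <- (0:(M - 1L)) * period / M
  out <- matrix(rep(Re(X[1L, ]), each = M), M, ncol(X))
  if (nmax > 0L) {
    E <- exp(outer(t_k, 2i * pi * (1:nmax) / period))
    out <- out + 2 * Re(E %*% X[-1L, , drop = FALSE])
  }
  out
}

#' Second-order source spectra along a segment
#'
#' Builds the quadratic source terms of the second perturbation order from
#' a linear harmonic field on a segment's nodes. The time-domain fields
#' and their derivatives are reconstructed spectrally (`p_t` from
#' `i w_n P_n`; `p_x` and `q_x` through the propagation equations), the
#' quadratic products are formed on a dealiased time grid of at least
#' `4 N` points, and the result is transformed back to harmonics:
#' row 1 `= -(rho alpha / A^2)(2 q q_x - q^2 A_x / A) - Dp p_x/(rho c^2)`
#' (optionally plus the small viscosity-nonlinearity cross term
#' `(4 pi nu gamma / (c^2 A^2)) Dp q`), and
#' row 2 `= -delta_1 (A / (rho^2 c^4)) Dp p_t`, with `Dp` the pressure
#' perturbation from the wall-law reference pressure.
#'
#' @param solution A `pulse_solution` (linear pass).
#' @param segment Segment id.
#' @param alpha Convection (Coriolis) profile coefficient, default 4/3.
#' @param include_viscous_cross_term Include the third addend of row 1
#'   (off by default; it is relatively small).
#' @param gamma_cross Constant friction coefficient used in the cross
#'   term's time-domain product.
#' @return List with complex `(N+1) x n_nodes` matrices `N1`, `N2`.
#' @export
nonlinear_source <- function(solution, segment, alpha = 4 / 3,
                             include_viscous_cross_term = FALSE,
                             gamma_cross = 4) {
  na <- node_amplitudes(solution, segment)
  phi <- phi_matrix(solution, segment)
  seg <- solution$network$segments[[segment]]
  delta1 <- segment_delta1(seg)
  p_ref <- if (!is.null(seg$wall)) seg$wall$p_0 else 0
  nonlinear_source_core(seg, na$P, na$Q, solution$period,
                        solution$network$fluid, phi, alpha, delta1,
                        include_viscous_cross_term, gamma_cross, p_ref)
}

segment_delta1 <- function(seg) {
  if (is.null(seg$wall)) return(0.5)   # constant-stiffness default
  delta_coefficients(seg$wall)$delta1
}

# phi_n at every node for n = 1..N (matrix N x n_nodes)
phi_matrix <- function(solution, segment) {
  nmax <- solution$n_max
  nn <- solution$network$segments[[segment]]$n_elements + 1L
  if (nmax == 0L) return(matrix(0i, 0L, nn))
  t(vapply(seq_len(nmax),
           function(n) solution$harmonics[[n + 1L]][[segment]]$phi,
           complex(nn)))
}

nonlinear_source_core <- function(seg, P, Q, period, props, phi,
                                  alpha = 4 / 3, delta1 = 0.5,
                                  include_viscous_cross_term = FALSE,
                                  gamma_cross = 4, p_ref = 0) {
  nmax <- nrow(P) - 1L
  if (nrow(phi) != nmax)
    stop("phi matrix must have one row per nonzero harmonic")
  M <- max(4L * nmax + 4L, 16L)
  A <- pi * seg$a^2
  cv <- seg$c
  Ax <- segment_dAdx(seg)
  rho <- props$rho
  omega <- 2 * pi * (0:nmax) / period
  # derivative amplitude matrices
  Pt <- (1i * omega) * P
  Px <- matrix(0i, nmax + 1L, ncol(P))
  Px[1L, ] <- -8 * pi * props$mu * Q[1L, ] / A^2
  if (nmax > 0L)
    Px[-1L, ] <- sweep(phi^2 * Q[-1L, , drop = FALSE], 2L, A / rho, `/`) *
      (-1i * omega[-1L])
  Qx <- matrix(0i, nmax + 1L, ncol(P))
  if (nmax > 0L)
    Qx[-1L, ] <- sweep(P[-1L, , drop = FALSE], 2L, A / (rho * cv^2), `*`) *
      (-1i * omega[-1L])
  # time-domain fields (M x n_nodes)
  p <- reconstruct_matrix(P, period, M)
  q <- reconstruct_matrix(Q, period, M)
  pt <- reconstruct_matrix(Pt, period, M)
  px <- reconstruct_matrix(Px, period, M)
  qx <- reconstruct_matrix(Qx, period, M)
  dp <- p - p_ref
  r1 <- -sweep(2 * q * qx - sweep(q^2, 2L, Ax / A, `*`), 2L, rho * alpha / A^2,
               `*`) -
    dp * px / sweep(matrix(1, M, ncol(P)), 2L, rho * cv^2, `*`)
  if (include_viscous_cross_term)
    r1 <- r1 + sweep(dp * q, 2L,
                     4 * pi * props$nu * gamma_cross / (cv^2 * A^2), `*`)
  r2 <- -sweep(dp * pt, 2L, delta1 * A / (rho^2 * cv^4), `*`)
  list(N1 = stats::mvfft(r1)[seq_len(nmax + 1L), , drop = FALSE] / M,
       N2 = stats::mvfft(r2)[seq_len(nmax + 1L), , drop = FALSE] / M)
}

#' Quadrature solution of the inhomogeneous correction equations
#'
#' Integrates the second-order per-harmonic equations along a segment with
#' zero initial conditions at the segment inlet, by variation of
#' parameters through the node transmission matrices and cumulative
#' trapezoidal quadrature of the source determinants; the steady
#' component is a direct cumulative trapezoid of its source rows.
#'
#' @param solution A `pulse_solution` (linear pass).
#' @param segment Segment id.
#' @param source Output of [nonlinear_source()] for the same segment.
#' @return List with complex `(N+1) x n_nodes` matrices `P2`, `Q2`;
#'   column 1 (the segment inlet) is identically zero.
#' @export
correction_quadrature <- function(solution, segment, source) {
  seg <- solution$network$segments[[segment]]
  x <- seg$x
  nn <- length(x)
  nmax <- solution$n_max
  P2 <- matrix(0i, nmax + 1L, nn)
  Q2 <- P2
  P2[1L, ] <- cumtrapz_c(x, source$N1[1L, ])
  Q2[1L, ] <- cumtrapz_c(x, source$N2[1L, ])
  for (n in seq_len(nmax)) {
    Tn <- solution$harmonics[[n + 1L]][[segment]]$T_nodes
    N1 <- source$N1[n + 1L, ]; N2 <- source$N2[n + 1L, ]
    B1 <- complex(nn); B2 <- complex(nn)
    for (j in seq_len(nn)) {
      Tj <- Tn[, , j]
      dj <- det2(Tj)
      B1[j] <- (N1[j] * Tj[2L, 2L] - N2[j] * Tj[1L, 2L]) / dj
      B2[j] <- (Tj[1L, 1L] * N2[j] - Tj[2L, 1L] * N1[j]) / dj
    }
    C1 <- cumtrapz_c(x, B1); C2 <- cumtrapz_c(x, B2)
    for (j in seq_len(nn)) {
      Tj <- Tn[, , j]
      P2[n + 1L, j] <- Tj[1L, 1L] * C1[j] + Tj[1L, 2L] * C2[j]
      Q2[n + 1L, j] <- Tj[2L, 1L] * C1[j] + Tj[2L, 2L] * C2[j]
    }
  }
  list(P2 = P2, Q2 = Q2)
}

cumtrapz_c <- function(x, y) {
  c(0i, cumsum(diff(x) * (y[-length(y)] + y[-1L]) / 2))
}

#' Junction velocity-head correction spectra
#'
#' For every junction, the total-pressure matching at second order brings
#' in the harmonic spectra of `rho u^2 / 2` differences between the first
#' parent's outlet and every other endpoint (other parents' outlets,
#' daughters' inlets), with `u = q^(1)/A` reconstructed in time and
#' re-transformed.
#'
#' @param solution A `pulse_solution` (linear pass).
#' @return List over junctions; each element is a named list (by endpoint
#'   segment id) of complex vectors over harmonics `0..N`.
#' @export
junction_correction_terms <- function(solution) {
  net <- solution$network
  rho <- net$fluid$rho
  nmax <- solution$n_max
  M <- max(4L * nmax + 4L, 16L)
  u2_spec <- function(id, at_outlet) {
    seg <- net$segments[[id]]
    x <- if (at_outlet) seg$length else 0
    hf <- harmonic_field(structure(solution, class = "pulse_solution"),
                         id, x, include_corrections = FALSE)
    A <- pi * (if (at_outlet) seg$a[seg$n_elements + 1L] else seg$a[1L])^2
    u <- fourier_reconstruct(hf$Q / A, (0:(M - 1L)) * solution$period / M,
                             solution$period)
    stats::fft(u^2)[seq_len(nmax + 1L)] / M
  }
  lapply(net$junctions, function(j) {
    p1 <- j$parents[1L]
    ref <- u2_spec(p1, TRUE)
    out <- list()
    for (p in j$parents[-1L])
      out[[p]] <- (rho / 2) * (ref - u2_spec(p, TRUE))
    for (d in j$daughters)
      out[[d]] <- (rho / 2) * (ref - u2_spec(d, FALSE))
    out
  })
}

#' Solve the network with second-order nonlinear corrections
#'
#' Two-pass perturbation solve: the linear pass of [solve_linear()], then
#' the correction fields along every segment ([nonlinear_source()] and
#' [correction_quadrature()]) and the junction velocity-head spectra
#' ([junction_correction_terms()]), and finally a second pass through the
#' same per-harmonic boundary systems whose right-hand sides carry the
#' segment-end corrections. The returned solution's amplitudes are the
#' corrected ones; [evaluate_waveform()] adds the interior node
#' corrections automatically.
#'
#' @param network A [network_model()].
#' @param n_harmonics Number of harmonics, see [solve_linear()].
#' @param alpha Convection coefficient (default 4/3).
#' @param include_viscous_cross_term See [nonlinear_source()].
#' @return A `pulse_solution` with a `corrections` component; the linear
#'   inlet amplitudes are kept in `P_hat_linear`, `Q_hat_linear`.
#' @export
solve_with_corrections <- function(network, n_harmonics = NULL,
                                   alpha = 4 / 3,
                                   include_viscous_cross_term = FALSE) {
  lin <- solve_linear(network, n_harmonics)
  ids <- names(network$segments)
  fields <- list(); P2_end <- list(); Q2_end <- list()
  for (id in ids) {
    src <- nonlinear_source(lin, id, alpha, include_viscous_cross_term)
    cf <- correction_quadrature(lin, id, src)
    fields[[id]] <- cf
    nn <- ncol(cf$P2)
    P2_end[[id]] <- cf$P2[, nn]
    Q2_end[[id]] <- cf$Q2[, nn]
  }
  N_junction <- junction_correction_terms(lin)
  nmax <- lin$n_max
  P_hat <- lin$P_hat; Q_hat <- lin$Q_hat
  slice <- function(lst, n) lapply(lst, function(v) v[n + 1L])
  for (n in 0:nmax) {
    corr_n <- list(
      P2_end = slice(P2_end, n),
      Q2_end = slice(Q2_end, n),
      N_junction = lapply(N_junction, slice, n = n))
    if (n == 0L) {
      sol <- if (network$zeroth$closure == "murray")
        solve_zeroth_murray_corrected(network, lin$harmonics[[1L]],
                                      lin$inlet_spectrum$amplitudes[1L],
                                      corr_n)
      else
        solve_zeroth(network, lin$harmonics[[1L]],
                     lin$inlet_spectrum$amplitudes[1L], corr_n)
    } else {
      omega <- 2 * pi * n / lin$period
      sol <- solve_harmonic(network, omega, lin$harmonics[[n + 1L]],
                            lin$inlet_spectrum$amplitudes[n + 1L], corr_n)
    }
    P_hat[n + 1L, ] <- sol$P; Q_hat[n + 1L, ] <- sol$Q
  }
  out <- lin
  out$P_hat_linear <- lin$P_hat
  out$Q_hat_linear <- lin$Q_hat
  out$P_hat <- P_hat
  out$Q_hat <- Q_hat
  out$corrections <- list(fields = fields, P2_end = P2_end,
                          Q2_end = Q2_end, N_junction = N_junction,
                          alpha = alpha,
                          include_viscous_cross_term = include_viscous_cross_term)
  out
}

# Murray closure with corrected outlet flows and total-pressure terms.
solve_zeroth_murray_corrected <- function(network, T0, inlet_amp, corr) {
  base <- solve_zeroth_murray(network, T0, inlet_amp)
  ids <- names(network$segments)
  xi <- network$zeroth$xi
  Q <- stats::setNames(base$Q, ids)
  P <- stats::setNames(base$P, ids)
  by_parent <- stats::setNames(network$junctions,
                               vapply(network$junctions,
                                      function(j) j$parents[1L], ""))
  jn_index <- stats::setNames(seq_along(network$junctions),
                              names(by_parent))
  advance <- function(s) {
    j <- by_parent[[s]]
    if (is.null(j)) return(invisible(NULL))
    jn <- jn_index[[s]]
    qL <- Q[[s]] + corr$Q2_end[[s]]
    pL <- P[[s]] + T0[[s]][1L, 2L] * Q[[s]] + corr$P2_end[[s]]
    ad <- vapply(j$daughters, function(d) network$segments[[d]]$a[1L], 0)
    w <- ad^xi / sum(ad^xi)
    for (k in seq_along(j$daughters)) {
      d <- j$daughters[k]
      Q[[d]] <<- qL * w[k]
      P[[d]] <<- pL + (corr$N_junction[[jn]][[d]] %||% 0i)
      advance(d)
    }
  }
  advance(network$inlet$segment)
  list(P = unname(P), Q = unname(Q), residual = 0)
}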