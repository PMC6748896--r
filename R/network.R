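# ---- network model ---------------------------------------------------------

#' Arterial network model
#'
#' Assembles segments, junction topology and boundary conditions into a
#' validated model ready for the per-harmonic solver.
#'
#' @param segments List of [vessel_segment()] objects.
#' @param junctions List of junctions, each `list(parents =, daughters =)`
#'   giving segment ids; a junction may merge several parents into one or
#'   more daughters.
#' @param inlet `list(segment =, kind =, spectrum = | values =, period =)`.
#'   `kind` is one of `"pressure_full"`, `"pressure_forward"`,
#'   `"flow_full"`, `"flow_forward"`; the waveform is given either as a
#'   [harmonic_spectrum()] or as uniform samples `values` over one
#'   `period` (decomposed on demand).
#' @param outlets Named list (by terminal segment id) of outlet models:
#'   `list(model = "windkessel3", R1 =, R2 =, C =)`,
#'   `list(model = "resistance", R_out =, p_out = 0)` or
#'   `list(model = "non_reflecting")`.
#' @param fluid [fluid_properties()].
#' @param zeroth Steady-component closure:
#'   `list(closure = "resistance", p_out = 0)` (default; uses the outlet
#'   resistances) or `list(closure = "murray", xi = 3,
#'   inlet_mean_pressure =)`.
#' @param gamma_mode Friction model for nonzero harmonics: `"womersley"`
#'   (default), a number for constant gamma, or `"inviscid"`. The steady
#'   component always uses the Poiseuille value 4 through the viscosity.
#' @return An object of class `network_model`.
#' @export
network_model <- function(segments, junctions = list(), inlet, outlets,
                          fluid = fluid_properties(),
                          zeroth = list(closure = "resistance"),
                          gamma_mode = "womersley") {
  names(segments) <- vapply(segments, `[[`, "", "id")
  ids <- names(segments)
  stopifnot(!anyDuplicated(ids))
  inlet$kind <- match.arg(inlet$kind, c("pressure_full", "pressure_forward",
                                        "flow_full", "flow_forward"))
  if (!inlet$segment %in% ids)
    stop(sprintf("inlet segment '%s' not found", inlet$segment))
  daughters <- unlist(lapply(junctions, `[[`, "daughters"))
  parents <- unlist(lapply(junctions, `[[`, "parents"))
  for (id in c(daughters, parents))
    if (!id %in% ids) stop(sprintf("junction references unknown segment '%s'", id))
  if (anyDuplicated(daughters))
    stop("a segment appears as daughter of more than one junction")
  if (inlet$segment %in% daughters)
    stop("the inlet segment cannot be a junction daughter")
  non_inlet <- setdiff(ids, inlet$segment)
  if (!setequal(daughters, non_inlet))
    stop("every non-inlet segment must be the daughter of exactly one junction")
  terminals <- setdiff(ids, parents)
  missing_out <- setdiff(terminals, names(outlets))
  if (length(missing_out))
    stop(sprintf("terminal segment(s) without outlet model: %s",
                 paste(missing_out, collapse = ", ")))
  extra_out <- setdiff(names(outlets), terminals)
  if (length(extra_out))
    stop(sprintf("outlet model given for non-terminal segment(s): %s",
                 paste(extra_out, collapse = ", ")))
  for (o in outlets)
    o$model <- match.arg(o$model, c("windkessel3", "resistance",
                                    "non_reflecting"))
  zeroth$closure <- match.arg(zeroth$closure %||% "resistance",
                              c("resistance", "murray"))
  if (is.null(zeroth$xi)) zeroth$xi <- 3
  if (is.null(zeroth$p_out)) zeroth$p_out <- 0
  structure(list(segments = segments, junctions = junctions, inlet = inlet,
                 outlets = outlets, fluid = fluid, zeroth = zeroth,
                 gamma_mode = gamma_mode, terminals = terminals),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d segment(s), %d junction(s), inlet '%s' (%s)\n",
              length(x$segments), length(x$junctions), x$inlet$segment,
              x$inlet$kind))
  invisible(x)
}

# inlet spectrum with at least n_max harmonics
inlet_spectrum <- function(network, n_max) {
  inl <- network$inlet
  if (!is.null(inl$spectrum)) {
    sp <- inl$spectrum
    if (sp$n_max < n_max)
      sp$amplitudes <- c(sp$amplitudes, rep(0i, n_max - sp$n_max))
    sp$n_max <- max(sp$n_max, n_max)
    return(sp)
  }
  fourier_decompose(inl$values, inl$period, n_max = n_max,
                    quantity = if (grepl("pressure", inl$kind)) "pressure"
                               else "flow")
}

outlet_impedance <- function(out, omega, sh = NULL) {
  switch(out$model,
    windkessel3 = out$R1 + out$R2 / (1 + 1i * omega * out$R2 * out$C),
    resistance = out$R_out + 0i,
    non_reflecting = sh$Z_out / (1 - 1i * sh$zeta_out))
}

outlet_zero_resistance <- function(out) {
  switch(out$model,
    windkessel3 = out$R1 + out$R2,
    resistance = out$R_out,
    non_reflecting = 0)
}

outlet_zero_pressure <- function(out, default = 0) out$p_out %||% default

# ---- per-harmonic assembly and solve ---------------------------------------

# Assemble and solve the 2*Ns system for harmonic n (omega > 0).
# sh: named list of segment_harmonic objects. rhs_extra: named list of
# per-row right-hand-side corrections (second perturbation pass), see
# solve_with_corrections().
solve_harmonic <- function(network, omega, sh, inlet_amp, corrections = NULL) {
  ids <- names(network$segments)
  ns <- length(ids)
  idx <- function(id) 2L * match(id, ids) - 1L   # P column; Q is +1
  M <- matrix(0i, 2L * ns, 2L * ns)
  rhs <- rep(0i, 2L * ns)
  r <- 0L
  corr_P2 <- function(id) if (is.null(corrections)) 0i else corrections$P2_end[[id]]
  corr_Q2 <- function(id) if (is.null(corrections)) 0i else corrections$Q2_end[[id]]
  corr_N <- function(jn, d) {
    if (is.null(corrections)) return(0i)
    corrections$N_junction[[jn]][[d]] %||% 0i
  }

  # inlet
  s1 <- network$inlet$segment
  shin <- sh[[s1]]
  r <- r + 1L
  switch(network$inlet$kind,
    pressure_full = { M[r, idx(s1)] <- 1; rhs[r] <- inlet_amp },
    pressure_forward = {
      M[r, idx(s1)] <- 1 + 1i * shin$zeta_in
      M[r, idx(s1) + 1L] <- shin$Z_in
      rhs[r] <- 2 * inlet_amp
    },
    flow_full = { M[r, idx(s1) + 1L] <- 1; rhs[r] <- inlet_amp },
    flow_forward = {
      M[r, idx(s1)] <- (1 + 1i * shin$zeta_in) / shin$Z_in
      M[r, idx(s1) + 1L] <- 1
      rhs[r] <- 2 * inlet_amp
    })

  # junctions: for each daughter, pressure continuity with the first
  # parent's outlet; parents 2.. tied to parent 1; one mass row.
  for (jn in seq_along(network$junctions)) {
    j <- network$junctions[[jn]]
    p1 <- j$parents[1L]
    T1 <- sh[[p1]]$T_full
    for (d in j$daughters) {
      r <- r + 1L
      M[r, idx(p1)] <- T1[1L, 1L]
      M[r, idx(p1) + 1L] <- T1[1L, 2L]
      M[r, idx(d)] <- -1
      rhs[r] <- -corr_N(jn, d) - corr_P2(p1)
    }
    for (p in j$parents[-1L]) {
      r <- r + 1L
      Tp <- sh[[p]]$T_full
      M[r, idx(p)] <- Tp[1L, 1L]
      M[r, idx(p) + 1L] <- Tp[1L, 2L]
      M[r, idx(p1)] <- M[r, idx(p1)] - T1[1L, 1L]
      M[r, idx(p1) + 1L] <- M[r, idx(p1) + 1L] - T1[1L, 2L]
      # equal total pressure among parents: move both corrections across
      rhs[r] <- corr_N(jn, p) - corr_P2(p) + corr_P2(p1)
    }
    r <- r + 1L
    for (p in j$parents) {
      Tp <- sh[[p]]$T_full
      M[r, idx(p)] <- M[r, idx(p)] + Tp[2L, 1L]
      M[r, idx(p) + 1L] <- M[r, idx(p) + 1L] + Tp[2L, 2L]
      rhs[r] <- rhs[r] - corr_Q2(p)
    }
    for (d in j$daughters)
      M[r, idx(d) + 1L] <- M[r, idx(d) + 1L] - 1
  }

  # outlets
  for (s in network$terminals) {
    out <- network$outlets[[s]]
    shs <- sh[[s]]
    Tm <- shs$T_full
    r <- r + 1L
    if (out$model == "non_reflecting") {
      zz <- 1 - 1i * shs$zeta_out
      M[r, idx(s)] <- zz * Tm[1L, 1L] - shs$Z_out * Tm[2L, 1L]
      M[r, idx(s) + 1L] <- zz * Tm[1L, 2L] - shs$Z_out * Tm[2L, 2L]
      rhs[r] <- -zz * corr_P2(s) + shs$Z_out * corr_Q2(s)
    } else {
      Zo <- outlet_impedance(out, omega, shs)
      M[r, idx(s)] <- Tm[1L, 1L] - Zo * Tm[2L, 1L]
      M[r, idx(s) + 1L] <- Tm[1L, 2L] - Zo * Tm[2L, 2L]
      rhs[r] <- -corr_P2(s) + Zo * corr_Q2(s)
    }
  }
  stopifnot(r == 2L * ns)
  solve_scaled(network, M, rhs, ids)
}

# Steady (n = 0) system using the Poiseuille transmission matrices.
solve_zeroth <- function(network, T0, inlet_amp, corrections = NULL) {
  ids <- names(network$segments)
  ns <- length(ids)
  idx <- function(id) 2L * match(id, ids) - 1L
  corr_P2 <- function(id) if (is.null(corrections)) 0i else corrections$P2_end[[id]]
  corr_Q2 <- function(id) if (is.null(corrections)) 0i else corrections$Q2_end[[id]]
  corr_N <- function(jn, d) {
    if (is.null(corrections)) return(0i)
    corrections$N_junction[[jn]][[d]] %||% 0i
  }
  M <- matrix(0i, 2L * ns, 2L * ns)
  rhs <- rep(0i, 2L * ns)
  r <- 1L
  s1 <- network$inlet$segment
  if (grepl("pressure", network$inlet$kind)) {
    M[r, idx(s1)] <- 1
  } else {
    M[r, idx(s1) + 1L] <- 1
  }
  rhs[r] <- inlet_amp   # forward kinds fall back to the full-value row at n=0
  for (jn in seq_along(network$junctions)) {
    j <- network$junctions[[jn]]
    p1 <- j$parents[1L]
    T1 <- T0[[p1]]
    for (d in j$daughters) {
      r <- r + 1L
      M[r, idx(p1)] <- 1
      M[r, idx(p1) + 1L] <- T1[1L, 2L]
      M[r, idx(d)] <- -1
      rhs[r] <- -corr_N(jn, d) - corr_P2(p1)
    }
    for (p in j$parents[-1L]) {
      r <- r + 1L
      M[r, idx(p)] <- 1
      M[r, idx(p) + 1L] <- T0[[p]][1L, 2L]
      M[r, idx(p1)] <- M[r, idx(p1)] - 1
      M[r, idx(p1) + 1L] <- M[r, idx(p1) + 1L] - T1[1L, 2L]
      rhs[r] <- corr_N(jn, p) - corr_P2(p) + corr_P2(p1)
    }
    r <- r + 1L
    for (p in j$parents) {
      M[r, idx(p) + 1L] <- M[r, idx(p) + 1L] + 1
      rhs[r] <- rhs[r] - corr_Q2(p)
    }
    for (d in j$daughters)
      M[r, idx(d) + 1L] <- M[r, idx(d) + 1L] - 1
  }
  for (s in network$terminals) {
    out <- network$outlets[[s]]
    r <- r + 1L
    R0 <- outlet_zero_resistance(out)
    M[r, idx(s)] <- 1
    M[r, idx(s) + 1L] <- T0[[s]][1L, 2L] - R0
    rhs[r] <- outlet_zero_pressure(out, network$zeroth$p_out) -
      corr_P2(s) + R0 * corr_Q2(s)
  }
  stopifnot(r == 2L * ns)
  solve_scaled(network, M, rhs, ids)
}

# Column scaling (pressure by rho c^2, flow by A c) for conditioning.
solve_scaled <- function(network, M, rhs, ids) {
  sc <- numeric(2L * length(ids))
  for (s in seq_along(ids)) {
    seg <- network$segments[[ids[s]]]
    sc[2L * s - 1L] <- network$fluid$rho * mean(seg$c)^2
    sc[2L * s] <- pi * seg$a[1L]^2 * seg$c[1L]
  }
  Ms <- sweep(M, 2L, sc, `*`)
  y <- tryCatch(solve(Ms, rhs), error = function(e)
    stop(sprintf("singular boundary system: %s", conditionMessage(e))))
  x <- y * sc
  res <- max(Mod(M %*% x - rhs)) / max(Mod(rhs), 1e-300)
  list(P = x[seq(1L, length(x), 2L)], Q = x[seq(2L, length(x), 2L)],
       residual = res)
}

# Murray's-law steady closure on a tree: split mean flows by radius^xi and
# march mean pressures from the inlet through the Poiseuille drops.
solve_zeroth_murray <- function(network, T0, inlet_amp) {
  if (any(vapply(network$junctions, function(j) length(j$parents), 1L) > 1L))
    stop("Murray closure is not applicable to merging junctions")
  if (!grepl("flow", network$inlet$kind))
    stop("Murray closure requires a flow inlet waveform")
  pbar <- network$zeroth$inlet_mean_pressure
  if (is.null(pbar))
    stop("Murray closure requires zeroth$inlet_mean_pressure")
  xi <- network$zeroth$xi
  ids <- names(network$segments)
  Q <- stats::setNames(rep(NA_complex_, length(ids)), ids)
  P <- stats::setNames(rep(NA_complex_, length(ids)), ids)
  Q[network$inlet$segment] <- inlet_amp
  P[network$inlet$segment] <- pbar
  by_parent <- stats::setNames(network$junctions,
                               vapply(network$junctions,
                                      function(j) j$parents[1L], ""))
  advance <- function(s) {
    pL <- P[[s]] + T0[[s]][1L, 2L] * Q[[s]]
    j <- by_parent[[s]]
    if (is.null(j)) return(invisible(NULL))
    ad <- vapply(j$daughters,
                 function(d) network$segments[[d]]$a[1L], 0)
    w <- ad^xi / sum(ad^xi)
    for (k in seq_along(j$daughters)) {
      d <- j$daughters[k]
      Q[[d]] <<- Q[[s]] * w[k]
      P[[d]] <<- pL
      advance(d)
    }
  }
  advance(network$inlet$segment)
  list(P = unname(P), Q = unname(Q), residual = 0)
}

#' Murray's-law flow split at a junction
#'
#' Splits a parent mean flow among daughter branches proportionally to
#' `a^xi` of the daughter inlet radii (`xi = 3` for laminar optimality,
#' 2.76 is often quoted for arterial blood flow).
#'
#' @param parent_flow Mean flow to distribute (m^3/s).
#' @param radii Daughter inlet radii (m).
#' @param xi Exponent.
#' @return Vector of daughter flows summing to `parent_flow`.
#' @export
murray_split <- function(parent_flow, radii, xi = 3) {
  stopifnot(length(radii) >= 1L, all(radii > 0), xi > 0)
  parent_flow * radii^xi / sum(radii^xi)
}

#' Solve the linearized network problem
#'
#' For each harmonic `n = 0..N` assembles the `2 Ns` boundary equations
#' (inlet, junction continuity and mass conservation, outlet impedances;
#' Poiseuille transmission for `n = 0`) and solves the dense complex
#' system for the segment inlet amplitudes.
#'
#' @param network A [network_model()].
#' @param n_harmonics Number of harmonics `N`; defaults to the inlet
#'   spectrum's own count (or its 99.99%-energy count for sampled input).
#' @return Object of class `pulse_solution` with complex matrices `P_hat`,
#'   `Q_hat` (`(N+1) x Ns`), the per-harmonic segment data, and the worst
#'   residual.
#' @export
solve_linear <- function(network, n_harmonics = NULL) {
  inl <- network$inlet
  sp0 <- if (!is.null(inl$spectrum)) inl$spectrum
         else fourier_decompose(inl$values, inl$period)
  n_max <- n_harmonics %||% sp0$n_max
  spec <- inlet_spectrum(network, n_max)
  ids <- names(network$segments)
  ns <- length(ids)
  P_hat <- matrix(0i, n_max + 1L, ns, dimnames = list(NULL, ids))
  Q_hat <- P_hat
  sh_all <- vector("list", n_max + 1L)
  # steady component
  T0 <- lapply(network$segments, zeroth_transmission, mu = network$fluid$mu)
  z0 <- if (network$zeroth$closure == "murray")
    solve_zeroth_murray(network, T0, spec$amplitudes[1L])
  else
    solve_zeroth(network, T0, spec$amplitudes[1L])
  P_hat[1L, ] <- z0$P; Q_hat[1L, ] <- z0$Q
  worst <- z0$residual
  sh_all[[1L]] <- T0
  for (n in seq_len(n_max)) {
    omega <- 2 * pi * n / spec$period
    sh <- lapply(network$segments, segment_transmission, omega = omega,
                 props = network$fluid, gamma_mode = network$gamma_mode)
    sol <- solve_harmonic(network, omega, sh, spec$amplitudes[n + 1L])
    P_hat[n + 1L, ] <- sol$P; Q_hat[n + 1L, ] <- sol$Q
    worst <- max(worst, sol$residual)
    sh_all[[n + 1L]] <- sh
  }
  structure(list(network = network, period = spec$period, n_max = n_max,
                 inlet_spectrum = spec,
                 P_hat = P_hat, Q_hat = Q_hat, harmonics = sh_all,
                 residual = worst, corrections = NULL),
            class = "pulse_solution")
}

#' @export
print.pulse_solution <- function(x, ...) {
  cat(sprintf("<pulse_solution> %d segment(s), N = %d harmonics, T = %g s%s\n",
              ncol(x$P_hat), x$n_max, x$period,
              if (!is.null(x$corrections)) ", with second-order corrections"
              else ""))
  cat(sprintf("  worst boundary residual: %.2e\n", x$residual))
  invisible(x)
}

#' Harmonic amplitudes of pressure and flow at a site
#'
#' Evaluates `[P_n(x), Q_n(x)] = T_n(x) [P^_n, Q^_n]` for all harmonics at
#' one position of one segment, optionally adding the second-order node
#' corrections when the solution carries them.
#'
#' @param solution A `pulse_solution`.
#' @param segment Segment id.
#' @param x Position from the segment inlet (m).
#' @param include_corrections Add `P2`, `Q2` (nearest node) if available.
#' @return List of complex vectors `P`, `Q` (length `N + 1`).
#' @export
harmonic_field <- function(solution, segment, x, include_corrections = TRUE) {
  seg <- solution$network$segments[[segment]]
  if (is.null(seg)) stop(sprintf("unknown segment '%s'", segment))
  if (x < -1e-12 || x > seg$length + 1e-12)
    stop("x outside the segment")
  nmax <- solution$n_max
  P <- complex(nmax + 1L); Q <- complex(nmax + 1L)
  v0 <- zeroth_transmission(seg, solution$network$fluid$mu, x) %*%
    c(solution$P_hat[1L, segment], solution$Q_hat[1L, segment])
  P[1L] <- v0[1L]; Q[1L] <- v0[2L]
  for (n in seq_len(nmax)) {
    Tn <- transmission_at(solution$harmonics[[n + 1L]][[segment]], x)
    v <- Tn %*% c(solution$P_hat[n + 1L, segment],
                  solution$Q_hat[n + 1L, segment])
    P[n + 1L] <- v[1L]; Q[n + 1L] <- v[2L]
  }
  if (include_corrections && !is.null(solution$corrections)) {
    cf <- solution$corrections$fields[[segment]]
    j <- which.min(abs(seg$x - x))
    P <- P + cf$P2[, j]
    Q <- Q + cf$Q2[, j]
  }
  list(P = P, Q = Q)
}

#' Time-domain waveforms at a site
#'
#' Reconstructs `p(t)` and `q(t)` at a position of a segment from the
#' solved harmonic amplitudes (plus second-order corrections if present).
#'
#' @inheritParams harmonic_field
#' @param times Evaluation instants (s).
#' @return `data.frame(time, p, q)` in SI units (Pa, m^3/s).
#' @export
evaluate_waveform <- function(solution, segment, x, times,
                              include_corrections = TRUE) {
  hf <- harmonic_field(solution, segment, x, include_corrections)
  data.frame(
    time = times,
    p = fourier_reconstruct(hf$P, times, solution$period),
    q = fourier_reconstruct(hf$Q, times, solution$period))
}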