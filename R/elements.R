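# ---- vessel segments -------------------------------------------------------

#' Discretized vessel segment
#'
#' Builds the piecewise-conic discretization of one vessel (or vessel
#' segment between junctions): `Ne = ceiling(L / h_b)` equal elements of
#' length `h = L / Ne`, with node radii obtained by interpolating between
#' the inlet and outlet radii and node pulse wave velocities either
#' constant or taken from an empirical PWV-radius relation.
#'
#' @param id Segment identifier (character).
#' @param length Segment length `L` (m).
#' @param a_in,a_out Inlet and outlet lumen radii (m).
#' @param element_length Basic element length `h_b` (m); default 1 cm.
#' @param interpolation Radius interpolation between the printed end radii:
#'   `"radius"` (linear in radius, default), `"area"` (linear in area) or
#'   `"exponential"`.
#' @param pwv Constant pulse wave velocity (m/s), or a vector over nodes.
#' @param pwv_law Name of an empirical relation accepted by
#'   [empirical_pwv()]; overrides `pwv`.
#' @param wall A [wall_law()] for nonlinear wall behaviour (optional; its
#'   `delta_1` feeds the second-order corrections).
#' @return An object of class `vessel_segment` with node positions `x`,
#'   radii `a`, wave speeds `c` and element lengths `h`.
#' @export
vessel_segment <- function(id, length, a_in, a_out = a_in,
                           element_length = 0.01,
                           interpolation = c("radius", "area", "exponential"),
                           pwv = NULL, pwv_law = NULL, wall = NULL) {
  interpolation <- match.arg(interpolation)
  stopifnot(length > 0, a_in > 0, a_out > 0, element_length > 0)
  ne <- max(1L, as.integer(ceiling(length / element_length - 1e-9)))
  x <- seq(0, length, length.out = ne + 1L)
  a <- interp_radius(x, length, a_in, a_out, interpolation)
  if (!is.null(pwv_law)) {
    cvec <- empirical_pwv(pwv_law, a)
  } else if (!is.null(pwv)) {
    cvec <- if (length(pwv) == 1L) rep(pwv, ne + 1L) else pwv
    stopifnot(length(cvec) == ne + 1L)
  } else if (!is.null(wall)) {
    cvec <- rep(wall$c_0, ne + 1L)
  } else stop("one of pwv, pwv_law or wall must provide the wave speed")
  stopifnot(all(cvec > 0))
  structure(list(id = id, length = length, x = x, a = a, c = cvec,
                 n_elements = ne, h = diff(x),
                 interpolation = interpolation, pwv_law = pwv_law,
                 wall = wall),
            class = "vessel_segment")
}

interp_radius <- function(x, L, a_in, a_out, interpolation) {
  s <- x / L
  switch(interpolation,
    radius = a_in + (a_out - a_in) * s,
    area = sqrt(a_in^2 + (a_out^2 - a_in^2) * s),
    exponential = a_in * (a_out / a_in)^s)
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("<vessel_segment> '%s': L = %g m, a = %.3g -> %.3g mm, %d element(s)\n",
              x$id, x$length, x$a[1L] * 1e3, x$a[x$n_elements + 1L] * 1e3,
              x$n_elements))
  invisible(x)
}

# radius / wave speed at arbitrary position (same interpolation as nodes)
segment_radius_at <- function(segment, x) {
  interp_radius(x, segment$length, segment$a[1L],
                segment$a[segment$n_elements + 1L], segment$interpolation)
}
segment_pwv_at <- function(segment, x) {
  if (!is.null(segment$pwv_law))
    empirical_pwv(segment$pwv_law, segment_radius_at(segment, x))
  else
    stats::approx(segment$x, segment$c, xout = x, rule = 2)$y
}

# ---- transmission matrices -------------------------------------------------

#' Transmission matrix of a uniform vessel
#'
#' `T(x) = [[cos kx, -i Z sin kx], [-i Y sin kx, cos kx]]` mapping inlet
#' harmonic amplitudes `(P(0), Q(0))` to position `x`; `Y = 1/Z` is the
#' characteristic admittance. `T(0)` is the identity and `det T = 1`.
#'
#' @param k Complex wavenumber (1/m).
#' @param Z Characteristic impedance (Pa s/m^3), nonzero.
#' @param x Position (m), `>= 0`.
#' @return Complex 2x2 matrix.
#' @export
uniform_transmission <- function(k, Z, x) {
  stopifnot(x >= 0)
  if (Mod(Z) == 0) stop("zero characteristic impedance")
  th <- k * x
  matrix(c(cos(th), -1i * sin(th) / Z,
           -1i * Z * sin(th), cos(th)),
         2L, 2L)
}

# Transmission matrix of one conic element, from endpoint values.
# Endpoint-mean rule: kbar = (omega/2)(phi0/c0 + phi1/c1), cbar, phibar
# endpoint averages; zeta evaluated at both element ends with the element's
# radius slope. theta_full = kbar * h. `frac` in (0,1] gives the partial
# element from its inlet to frac*h (used for mid-element evaluation).
conic_element_matrix <- function(a0, a1, h, omega, c0, c1, phi0, phi1, rho,
                                 frac = 1) {
  kbar <- (omega / 2) * (phi0 / c0 + phi1 / c1)
  cbar <- (c0 + c1) / 2
  phibar <- (phi0 + phi1) / 2
  if (Mod(kbar) == 0) stop("kbar = 0: use the zeroth-harmonic path")
  ax <- (a1 - a0) / h
  xe <- frac * h
  ae <- a0 + ax * xe                    # radius at element-local position
  z_in <- ax / (kbar * a0)              # zeta at element inlet
  z_e <- ax / (kbar * ae)               # zeta at evaluation point
  th <- kbar * xe
  Ybar <- pi * a0 * ae / (rho * cbar * phibar)
  t11 <- (a0 / ae) * cos(th) + z_e * sin(th)
  t12 <- -1i * sin(th) / Ybar
  t21 <- -1i * Ybar * ((1 + z_in * z_e) * sin(th) + (z_e - z_in) * cos(th))
  t22 <- (ae / a0) * (cos(th) - z_e * sin(th))
  matrix(c(t11, t21, t12, t22), 2L, 2L)
}

#' Transmission matrix of a single conic element
#'
#' Closed-form per-element matrix of the piecewise-conic method: the wave
#' speed, viscous factor and wavenumber are frozen at their endpoint means
#' and the radius varies linearly across the element. Reduces exactly to
#' [uniform_transmission()] when `a_prev == a_next`.
#'
#' @param a_prev,a_next Element end radii (m).
#' @param h Element length (m).
#' @param omega Angular frequency (rad/s), `> 0`.
#' @param props [fluid_properties()].
#' @param c_prev,c_next Wave speeds at the element ends (m/s).
#' @param gamma_mode Friction model: `"womersley"` (default), a number for
#'   constant gamma, or `"inviscid"`.
#' @return Complex 2x2 matrix.
#' @export
conic_element_transmission <- function(a_prev, a_next, h, omega, props,
                                       c_prev, c_next = c_prev,
                                       gamma_mode = "womersley") {
  stopifnot(a_prev > 0, a_next > 0, h > 0, omega > 0)
  gfun <- resolve_gamma_mode(gamma_mode)
  phi0 <- node_phi(a_prev, omega, props, gfun)
  phi1 <- node_phi(a_next, omega, props, gfun)
  conic_element_matrix(a_prev, a_next, h, omega, c_prev, c_next,
                       phi0, phi1, props$rho)
}

node_phi <- function(a, omega, props, gfun) {
  if (props$nu == 0) return(1 + 0i)
  viscous_factor(a, omega, props$nu, gfun(a, omega, props$nu))
}

#' Per-harmonic propagation data of a segment
#'
#' Computes, for one angular frequency, the cumulative transmission
#' matrices `T(x_j) = T_j ... T_1` at every node of a discretized segment,
#' together with the element means and the inlet/outlet characteristic
#' impedances and taper parameters `zeta` needed by the network boundary
#' equations.
#'
#' @param segment A [vessel_segment()].
#' @param omega Angular frequency (rad/s), `> 0` (use
#'   [zeroth_transmission()] for the steady component).
#' @param props [fluid_properties()].
#' @param gamma_mode See [conic_element_transmission()].
#' @return List of class `segment_harmonic` with `T_nodes`
#'   (2 x 2 x (Ne+1) complex array, identity first), `T_full`, `Z_in`,
#'   `zeta_in`, `Z_out`, `zeta_out`, `phi` and `kbar` per element.
#' @export
segment_transmission <- function(segment, omega, props,
                                 gamma_mode = "womersley") {
  stopifnot(inherits(segment, "vessel_segment"), omega > 0)
  gfun <- resolve_gamma_mode(gamma_mode)
  ne <- segment$n_elements
  a <- segment$a; cv <- segment$c; h <- segment$h
  phi <- vapply(seq_len(ne + 1L),
                function(i) node_phi(a[i], omega, props, gfun),
                complex(1))
  rho <- props$rho
  Tn <- array(0i, c(2L, 2L, ne + 1L))
  Tn[, , 1L] <- diag(2)
  kbar <- complex(ne)
  for (i in seq_len(ne)) {
    Ti <- conic_element_matrix(a[i], a[i + 1L], h[i], omega,
                               cv[i], cv[i + 1L], phi[i], phi[i + 1L], rho)
    Tn[, , i + 1L] <- Ti %*% Tn[, , i]
    kbar[i] <- (omega / 2) * (phi[i] / cv[i] + phi[i + 1L] / cv[i + 1L])
  }
  ax1 <- (a[2L] - a[1L]) / h[1L]
  axn <- (a[ne + 1L] - a[ne]) / h[ne]
  cbar1 <- (cv[1L] + cv[2L]) / 2; phib1 <- (phi[1L] + phi[2L]) / 2
  cbarn <- (cv[ne] + cv[ne + 1L]) / 2; phibn <- (phi[ne] + phi[ne + 1L]) / 2
  structure(list(
    segment = segment, omega = omega,
    T_nodes = Tn, T_full = Tn[, , ne + 1L],
    Z_in = rho * cbar1 * phib1 / (pi * a[1L]^2),
    zeta_in = ax1 / (kbar[1L] * a[1L]),
    Z_out = rho * cbarn * phibn / (pi * a[ne + 1L]^2),
    zeta_out = axn / (kbar[ne] * a[ne + 1L]),
    phi = phi, kbar = kbar, rho = rho), class = "segment_harmonic")
}

#' Transmission matrix at an interior position
#'
#' Cumulative matrix `T(x)` of a [segment_transmission()] result at any
#' `x` in `[0, L]`, composing the node products with a partial element.
#'
#' @param sh A `segment_harmonic` object.
#' @param x Position from the segment inlet (m).
#' @return Complex 2x2 matrix.
#' @export
transmission_at <- function(sh, x) {
  seg <- sh$segment
  stopifnot(x >= -1e-12, x <= seg$length + 1e-12)
  x <- min(max(x, 0), seg$length)
  nodes <- seg$x
  i <- findInterval(x, nodes, rightmost.closed = TRUE)  # element index
  if (i > seg$n_elements) i <- seg$n_elements
  if (abs(x - nodes[i]) < 1e-14) return(sh$T_nodes[, , i])
  frac <- (x - nodes[i]) / seg$h[i]
  a <- seg$a; cv <- seg$c; phi <- sh$phi
  Tp <- conic_element_matrix(a[i], a[i + 1L], seg$h[i], sh$omega,
                             cv[i], cv[i + 1L], phi[i], phi[i + 1L],
                             sh$rho, frac = frac)
  Tp %*% sh$T_nodes[, , i]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zeroth-harmonic (steady) transmission matrix
#'
#' For the mean-flow component the flow rate is constant along a segment
#' and the pressure obeys the Poiseuille drop, giving
#' `T_0(x) = [[1, -8 pi mu int_0^x dx/A^2], [0, 1]]`. The integral is
#' evaluated by the trapezoidal rule on the segment nodes.
#'
#' @param segment A [vessel_segment()].
#' @param mu Dynamic viscosity (Pa s).
#' @param x Position (m); defaults to the full length.
#' @return Real 2x2 matrix (returned as complex for uniformity).
#' @export
zeroth_transmission <- function(segment, mu, x = segment$length) {
  f <- 1 / (pi * segment$a^2)^2
  cumint <- cumtrapz(segment$x, f)
  I <- stats::approx(segment$x, cumint, xout = x, rule = 2)$y
  matrix(c(1 + 0i, 0i, -8 * pi * mu * I + 0i, 1 + 0i), 2L, 2L)
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2))
}

# determinant of a 2x2 complex matrix (base det() is numeric-only)
det2 <- function(M) M[1L, 1L] * M[2L, 2L] - M[1L, 2L] * M[2L, 1L]

#' Reference transmission matrix by adaptive ODE integration
#'
#' Integrates the per-harmonic propagation equations
#' `dP/dx = -i omega rho phi^2 Q / A`, `dQ/dx = -i omega A P / (rho c^2)`
#' with the two canonical initial vectors `(1, 0)` and `(0, 1)` using the
#' adaptive complex solver `deSolve::zvode`; the two solutions form the
#' columns of `T(x)`. This is the high-accuracy reference against which
#' the piecewise-conic product is validated.
#'
#' @param segment A [vessel_segment()].
#' @param omega Angular frequency (rad/s), `> 0`.
#' @param props [fluid_properties()].
#' @param gamma_mode See [conic_element_transmission()].
#' @param tol Relative and absolute tolerance.
#' @return Complex 2x2 matrix `T(L)`.
#' @export
ode_transmission <- function(segment, omega, props, gamma_mode = "womersley",
                             tol = 1e-10) {
  stopifnot(omega > 0, tol > 0)
  gfun <- resolve_gamma_mode(gamma_mode)
  rho <- props$rho
  # integrate the scaled state (P, Z0 Q) so both components are O(1) and the
  # absolute tolerance is meaningful; Z0 is the inlet characteristic impedance
  Z0 <- rho * segment$c[1L] / (pi * segment$a[1L]^2)
  deriv <- function(x, y, parms) {
    a <- segment_radius_at(segment, x)
    cv <- segment_pwv_at(segment, x)
    phi <- node_phi(a, omega, props, gfun)
    A <- pi * a^2
    list(c(-1i * omega * rho * phi^2 * (y[2L] / Z0) / A,
           -1i * omega * A * Z0 * y[1L] / (rho * cv^2)))
  }
  cols <- lapply(list(c(1 + 0i, 0i), c(0i, 1 + 0i)), function(y0) {
    sol <- deSolve::zvode(y = y0, times = c(0, segment$length), func = deriv,
                          parms = NULL, rtol = tol, atol = tol)
    c(sol[2L, 2L], sol[2L, 3L])
  })
  # unscale: column 1 had (P, Q) = (1, 0); column 2 is the (0, 1/Z0) run
  matrix(c(cols[[1L]][1L], cols[[1L]][2L] / Z0,
           cols[[2L]][1L] * Z0, cols[[2L]][2L]), 2L, 2L)
}

#' Reflection and transmission coefficients of a segment
#'
#' Places the segment between two matched uniform pipes (areas and wave
#' speeds equal to the segment's end values), sends a unit forward
#' pressure wave from the left and requires a purely forward wave on the
#' right. With `Y_L`, `Y_R` the flanking characteristic admittances and
#' `T` the full-segment matrix, the boundary matching
#' `P(0) = 1 + R`, `Q(0) = Y_L (1 - R)`, `P(L) = S`, `Q(L) = Y_R S`
#' gives a 2x2 linear system for the reflection `R` and transmission `S`
#' coefficients.
#'
#' @param segment A [vessel_segment()].
#' @param omega Angular frequency (rad/s).
#' @param props [fluid_properties()].
#' @param gamma_mode See [conic_element_transmission()].
#' @param method `"conic"` (piecewise-conic product) or `"ode"` (reference
#'   integrator).
#' @param tol Tolerance for the `"ode"` method.
#' @return List with complex `R` and `S`.
#' @export
reflection_transmission <- function(segment, omega, props,
                                    gamma_mode = "womersley",
                                    method = c("conic", "ode"), tol = 1e-10) {
  method <- match.arg(method)
  gfun <- resolve_gamma_mode(gamma_mode)
  ne <- segment$n_elements
  Tm <- if (method == "conic")
    segment_transmission(segment, omega, props, gamma_mode)$T_full
  else
    ode_transmission(segment, omega, props, gamma_mode, tol)
  aL <- segment$a[1L]; aR <- segment$a[ne + 1L]
  phiL <- node_phi(aL, omega, props, gfun)
  phiR <- node_phi(aR, omega, props, gfun)
  YL <- pi * aL^2 / (props$rho * segment$c[1L] * phiL)
  YR <- pi * aR^2 / (props$rho * segment$c[ne + 1L] * phiR)
  M <- matrix(c(Tm[1L, 1L] - Tm[1L, 2L] * YL, Tm[2L, 1L] - Tm[2L, 2L] * YL,
                -1 + 0i, -YR), 2L, 2L)
  rhs <- c(-(Tm[1L, 1L] + Tm[1L, 2L] * YL), -(Tm[2L, 1L] + Tm[2L, 2L] * YL))
  if (Mod(det2(M)) < 1e-300) stop("degenerate impedances")
  sol <- solve(M, rhs)
  list(R = sol[1L], S = sol[2L])
}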