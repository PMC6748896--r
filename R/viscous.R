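#' Blood (fluid) properties
#'
#' @param rho Density (kg/m^3).
#' @param nu Kinematic viscosity (m^2/s).
#' @return List with `rho`, `nu` and dynamic viscosity `mu = rho * nu`.
#' @export
fluid_properties <- function(rho = 1040, nu = 4e-6) {
  stopifnot(rho > 0, nu >= 0)
  structure(list(rho = rho, nu = nu, mu = rho * nu), class = "fluid_properties")
}

# Ratio J1(z)/J0(z) for complex z by the modified Lentz continued fraction
#   J1/J0 = 1/(2/z - 1/(4/z - 1/(6/z - ...)))
# (from the recurrence r_n = J_n/J_{n-1} = 1/(2n/z - r_{n+1})).
# Stable for the arguments arising here (z = w exp(3i pi/4)).
bessel_j1_j0_ratio <- function(z) {
  if (Mod(z) == 0) return(0 + 0i)
  tiny <- 1e-290
  fval <- tiny + 0i           # b_0 = 0
  C <- fval
  D <- 0 + 0i
  for (j in 1:10000) {
    a <- if (j == 1L) 1 + 0i else -1 + 0i
    b <- 2 * j / z
    D <- b + a * D
    if (Mod(D) < tiny) D <- tiny + 0i
    C <- b + a / C
    if (Mod(C) < tiny) C <- tiny + 0i
    D <- 1 / D
    delta <- C * D
    fval <- fval * delta
    if (Mod(delta - 1) < 4e-16) break
  }
  fval
}

#' Womersley friction coefficient
#'
#' Complex, frequency-dependent wall-friction coefficient `gamma(omega)` of
#' oscillatory laminar flow in a rigid circular pipe. With the Womersley
#' number `w = a sqrt(omega/nu)` and `Lambda = i^{3/2} w`, the oscillatory
#' velocity profile `u(r) ~ 1 - J0(Lambda r/a)/J0(Lambda)` gives
#' `gamma = -a u_r(a)/u_mean = -Lambda^2 r / (Lambda - 2 r)` where
#' `r = J1(Lambda)/J0(Lambda)`. The steady limit `omega = 0` returns the
#' Poiseuille value 4 exactly; for large `w`,
#' `gamma ~ w exp(i pi/4) / sqrt(2)` grows with the square root of
#' frequency.
#'
#' @param a Lumen radius (m).
#' @param omega Angular frequency (rad/s), `>= 0`.
#' @param nu Kinematic viscosity (m^2/s), `> 0`.
#' @return Complex friction coefficient.
#' @export
womersley_gamma <- function(a, omega, nu) {
  stopifnot(a > 0, omega >= 0, nu > 0)
  if (omega == 0) return(4 + 0i)
  w <- a * sqrt(omega / nu)
  if (w < 1e-3) {                       # series limit: 4 - Lambda^2/6
    lam2 <- -1i * w^2
    return(4 - lam2 / 6)
  }
  lam <- w * exp(3i * pi / 4)
  r <- bessel_j1_j0_ratio(lam)
  -lam^2 * r / (lam - 2 * r)
}

#' Viscous factor of a harmonic wave
#'
#' `phi = sqrt(1 - i 2 pi nu gamma / (omega A))`, principal branch selected
#' so that `Im(phi) <= 0`: the imaginary part encodes the viscous decay of
#' a forward-propagating wave. The zeroth harmonic (`omega = 0`) is handled
#' by the steady Poiseuille path and is rejected here.
#'
#' @param a Lumen radius (m).
#' @param omega Angular frequency (rad/s), `> 0`.
#' @param nu Kinematic viscosity (m^2/s).
#' @param gamma Friction coefficient (complex); defaults to the Womersley
#'   value for `(a, omega, nu)`.
#' @return Complex dimensionless factor.
#' @export
viscous_factor <- function(a, omega, nu, gamma = NULL) {
  if (omega <= 0)
    stop("viscous_factor requires omega > 0; the zeroth harmonic uses the Poiseuille path")
  if (nu == 0) return(1 + 0i)
  if (is.null(gamma)) gamma <- womersley_gamma(a, omega, nu)
  area <- pi * a^2
  phi <- sqrt(1 - 2i * pi * nu * gamma / (omega * area))
  if (Im(phi) > 0) phi <- -phi
  phi
}

#' Complex wavenumber
#'
#' `k = omega phi / c`, with the branch of `phi` guaranteeing
#' `Im(k) <= 0`, so the forward wave `exp(-i k x)` decays in `+x`.
#'
#' @param omega Angular frequency (rad/s), `> 0`.
#' @param c Pulse wave velocity (m/s).
#' @param phi Viscous factor, see [viscous_factor()].
#' @return Complex wavenumber (1/m).
#' @export
wavenumber <- function(omega, c, phi = 1 + 0i) {
  stopifnot(omega > 0, c > 0)
  omega * phi / c
}

#' Viscous characteristic frequency
#'
#' `omega_nu = 2 pi gamma nu / A`: below this angular frequency viscous
#' effects dominate the wave dynamics of a vessel.
#'
#' @param a Lumen radius (m).
#' @param nu Kinematic viscosity (m^2/s).
#' @param gamma Friction coefficient (defaults to Poiseuille/pulsatile
#'   effective value 4).
#' @return Angular frequency (rad/s).
#' @export
viscous_frequency <- function(a, nu, gamma = 4) {
  2 * pi * Re(gamma) * nu / (pi * a^2)
}

# Resolve a gamma-mode specification into a function gamma(a, omega).
# mode: "womersley", "constant" (with value), or a numeric -> constant.
resolve_gamma_mode <- function(gamma_mode) {
  if (is.function(gamma_mode)) return(gamma_mode)
  if (is.numeric(gamma_mode)) {
    val <- gamma_mode
    return(function(a, omega, nu) as.complex(val))
  }
  if (is.list(gamma_mode)) {
    if (identical(gamma_mode$mode, "constant"))
      return(resolve_gamma_mode(gamma_mode$value))
    gamma_mode <- gamma_mode$mode
  }
  if (identical(gamma_mode, "womersley"))
    return(function(a, omega, nu) womersley_gamma(a, omega, nu))
  if (identical(gamma_mode, "inviscid"))
    return(function(a, omega, nu) 0 + 0i)
  stop(sprintf("unknown gamma mode '%s'", as.character(gamma_mode)))
}
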