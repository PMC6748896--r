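# Independent oracles and shared builders for the test suite.

# Bessel J_nu of complex argument by the power series (moderate |z| only);
# independent of the continued-fraction evaluation used in the package.
bessel_j_series <- function(nu, z, n_terms = 200L) {
  s <- 0 + 0i
  term <- (z / 2)^nu / gamma(nu + 1)
  for (k in 0:n_terms) {
    s <- s + term
    term <- term * (-(z / 2)^2) / ((k + 1) * (k + 1 + nu))
  }
  s
}

# Womersley friction coefficient straight from the series profile.
womersley_gamma_series <- function(a, omega, nu) {
  w <- a * sqrt(omega / nu)
  lam <- w * exp(3i * pi / 4)
  r <- bessel_j_series(1, lam) / bessel_j_series(0, lam)
  -lam^2 * r / (lam - 2 * r)
}

# Direct numerical quadrature of the defining Fourier integral
# X_n = (1/T) int_0^T x(t) exp(-i w_n t) dt.
fourier_coef_quadrature <- function(f, period, n) {
  wre <- stats::integrate(function(t) f(t) * cos(2 * pi * n * t / period),
                          0, period, rel.tol = 1e-12,
                          subdivisions = 2000L)$value
  wim <- stats::integrate(function(t) -f(t) * sin(2 * pi * n * t / period),
                          0, period, rel.tol = 1e-12,
                          subdivisions = 2000L)$value
  complex(real = wre, imaginary = wim) / period
}

blood <- function(nu = 4e-6) fluid_properties(1040, nu)

carotid_cone_segment <- function(h = 0.005) {
  vessel_segment("cone", 0.094, 6.75e-3 / 2, 3.5e-3 / 2, element_length = h,
                 pwv_law = "blanco_biexp")
}
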