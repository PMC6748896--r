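#' Vessel wall constitutive law
#'
#' Describes the pressure-area relation `A(p)` of a compliant vessel around
#' its equilibrium state `(p_0, A_0)` with equilibrium pulse wave velocity
#' `c_0`, where `c_0^2 = A_0 / (rho A'(p_0))`. Available relations:
#'
#' * `constant_stiffness`: `p = p_0 + beta (sqrt(A) - sqrt(A_0))` with
#'   `beta = 2 rho c_0^2 / sqrt(A_0)` (strain-independent wall stiffness).
#' * `olufsen`: `p = p_0 + 2 rho c_0^2 (1 - sqrt(A_0/A))`.
#' * `power_law`: `p = p_0 + (2 rho c_0^2 / b) ((A/A_0)^{b/2} - 1)`;
#'   `b = 1` recovers `constant_stiffness` and `b = -1` recovers `olufsen`.
#' * `armentano`: logarithmic diameter law,
#'   `A = A_0 (1 + p_0/(2 rho c_0^2) log(p/p_0))^2`, requiring `p > 0`.
#' * `kholodov`: exponential law
#'   `p = p_0 + rho c_0^2 (exp(A/A_0 - 1) - 1)`, stated for `A >= A_0` and
#'   extended below `A_0` by the same smooth formula.
#'
#' @param kind One of `"constant_stiffness"`, `"olufsen"`, `"power_law"`,
#'   `"armentano"`, `"kholodov"`.
#' @param a_0 Equilibrium lumen radius (m); alternatively give `area_0`.
#' @param c_0 Equilibrium pulse wave velocity (m/s).
#' @param p_0 Reference (equilibrium) pressure (Pa).
#' @param rho Blood density (kg/m^3).
#' @param b Power-law exponent (only for `kind = "power_law"`).
#' @param area_0 Equilibrium area (m^2), overrides `a_0`.
#' @return An object of class `wall_law`.
#' @export
wall_law <- function(kind, a_0 = NULL, c_0, p_0 = 0, rho = 1040,
                     b = NULL, area_0 = NULL) {
  kind <- match.arg(kind, c("constant_stiffness", "olufsen", "power_law",
                            "armentano", "kholodov"))
  if (is.null(area_0)) {
    stopifnot(!is.null(a_0), a_0 > 0)
    area_0 <- pi * a_0^2
  }
  stopifnot(area_0 > 0, c_0 > 0, rho > 0)
  if (kind == "power_law") {
    stopifnot(!is.null(b), b != 0)
  } else if (!is.null(b)) {
    warning("exponent b ignored for kind != 'power_law'")
  }
  if (kind == "armentano" && p_0 <= 0)
    stop("the armentano law requires p_0 > 0")
  structure(list(kind = kind, area_0 = area_0, c_0 = c_0, p_0 = p_0,
                 rho = rho, b = b),
            class = "wall_law")
}

#' @export
print.wall_law <- function(x, ...) {
  cat(sprintf("<wall_law> %s: A0 = %.4g m^2 (a0 = %.4g mm), c0 = %.3g m/s, p0 = %.4g Pa%s\n",
              x$kind, x$area_0, sqrt(x$area_0 / pi) * 1e3, x$c_0, x$p_0,
              if (!is.null(x$b)) sprintf(", b = %.4g", x$b) else ""))
  invisible(x)
}

#' Lumen area from pressure
#'
#' Inverts the constitutive relation of a [wall_law()]. All inverses are in
#' closed form; see [pressure_from_area()] for the forward relations.
#'
#' @param law A [wall_law()].
#' @param p Pressure (Pa), vectorized.
#' @return Area (m^2).
#' @export
area_from_pressure <- function(law, p) {
  ph <- (p - law$p_0) / (law$rho * law$c_0^2)   # dimensionless perturbation
  a0 <- law$area_0
  switch(law$kind,
    constant_stiffness = {
      root <- 1 + ph / 2
      if (any(root <= 0)) stop("pressure below the collapse point of the law")
      a0 * root^2
    },
    olufsen = {
      den <- 1 - ph / 2
      if (any(den <= 0)) stop("pressure out of the olufsen law's domain")
      a0 / den^2
    },
    power_law = {
      base <- 1 + law$b * ph / 2
      if (any(base <= 0)) stop("pressure out of the power law's domain")
      a0 * base^(2 / law$b)
    },
    armentano = {
      if (any(p <= 0)) stop("armentano law requires p > 0")
      kap <- law$p_0 / (law$rho * law$c_0^2)
      a0 * (1 + (kap / 2) * log(p / law$p_0))^2
    },
    kholodov = {
      arg <- 1 + ph
      if (any(arg <= 0)) stop("pressure out of the kholodov law's domain")
      a0 * (1 + log(arg))
    })
}

#' Pressure from lumen area
#'
#' @param law A [wall_law()].
#' @param A Area (m^2), vectorized; must lie in the law's physical domain.
#' @return Pressure (Pa).
#' @export
pressure_from_area <- function(law, A) {
  stopifnot(all(A > 0))
  rc2 <- law$rho * law$c_0^2
  a0 <- law$area_0
  switch(law$kind,
    constant_stiffness = law$p_0 + 2 * rc2 * (sqrt(A / a0) - 1),
    olufsen = law$p_0 + 2 * rc2 * (1 - sqrt(a0 / A)),
    power_law = law$p_0 + (2 * rc2 / law$b) * ((A / a0)^(law$b / 2) - 1),
    armentano = {
      kap <- law$p_0 / rc2
      law$p_0 * exp((2 / kap) * (sqrt(A / a0) - 1))
    },
    kholodov = law$p_0 + rc2 * (exp(A / a0 - 1) - 1))
}

#' Nonlinearity coefficients of a wall law (closed form)
#'
#' The dimensionless coefficients `delta_1..delta_3` of the compliance
#' expansion about equilibrium,
#' `A'(p)/A'(p_0) = 1 + delta_1 p^ + delta_2 p^^2 + ...` with
#' `p^ = (p - p_0)/(rho c_0^2)`. In terms of the normalized derivatives
#' `g_k = (rho c_0^2)^k A^(k)(p_0) / A_0` they are
#' `delta_1 = g_2`, `delta_2 = g_3 / 2`, `delta_3 = g_4 / 2`.
#' Closed forms: power law (covering constant stiffness `b = 1`, for which
#' `(1/2, 0, 0)`, and the olufsen law `b = -1`, `(3/2, 3/2, 15/4)`)
#' `delta_1 = (2-b)/2`, `delta_2 = (b-1)(b-2)/4`,
#' `delta_3 = -(b-1)(b-2)(3b-2)/8`; armentano
#' `delta_1 = 1/2 - rho c_0^2/p_0`,
#' `delta_2 = (rho c_0^2/p_0)^2 - (3/4) rho c_0^2/p_0`; kholodov
#' `(-1, 1, -3)`.
#'
#' @param law A [wall_law()].
#' @return List with components `delta1`, `delta2`, `delta3`.
#' @seealso [delta_coefficients_numeric()] for the finite-difference route.
#' @export
delta_coefficients <- function(law) {
  out <- switch(law$kind,
    constant_stiffness = c(1 / 2, 0, 0),
    olufsen = c(3 / 2, 3 / 2, 15 / 4),
    power_law = {
      b <- law$b
      c((2 - b) / 2,
        (b - 1) * (b - 2) / 4,
        -(b - 1) * (b - 2) * (3 * b - 2) / 8)
    },
    armentano = {
      r <- law$rho * law$c_0^2 / law$p_0
      # delta_3 from one more derivative of the log law: g4 = kap(6-11kap/2+3kap^2)/... ;
      # computed numerically elsewhere, closed form kept to the printed two.
      c(1 / 2 - r, r^2 - 3 / 4 * r, NA_real_)
    },
    kholodov = c(-1, 1, -3))
  list(delta1 = out[1L], delta2 = out[2L], delta3 = out[3L])
}

#' Nonlinearity coefficients by numeric differentiation
#'
#' Independent evaluation of `delta_1..delta_3` from high-order central
#' finite differences of `A(p)` at `p_0`, with one Richardson extrapolation
#' step. Serves as the oracle for [delta_coefficients()] and covers laws
#' without printed closed forms.
#'
#' @param law A [wall_law()].
#' @param step Dimensionless pressure step `h` (in units of `rho c_0^2`).
#' @return List with `delta1`, `delta2`, `delta3`.
#' @export
delta_coefficients_numeric <- function(law, step = 0.02) {
  rc2 <- law$rho * law$c_0^2
  f <- function(s) area_from_pressure(law, law$p_0 + rc2 * s) / law$area_0
  if (step < 1e-4) stop("step underflow")
  g <- function(h) {
    s <- f(h * (-3:3))      # s[4] is f(0) = 1
    d2 <- (-s[6] + 16 * s[5] - 30 * s[4] + 16 * s[3] - s[2]) / (12 * h^2)
    d3 <- (-s[7] + 8 * s[6] - 13 * s[5] + 13 * s[3] - 8 * s[2] + s[1]) /
      (8 * h^3)
    d4 <- (-s[7] + 12 * s[6] - 39 * s[5] + 56 * s[4] - 39 * s[3] +
             12 * s[2] - s[1]) / (6 * h^4)
    c(d2, d3, d4)
  }
  d <- (16 * g(step / 2) - g(step)) / 15   # both stencils are O(h^4)
  list(delta1 = d[1L], delta2 = d[2L] / 2, delta3 = d[3L] / 2)
}

#' Power-law exponent from the collapse pressure
#'
#' `b = 2 rho c_0^2 / (p_0 - p_collapse)`: the exponent of the power-law
#' wall relation such that the vessel area vanishes at `p_collapse`.
#'
#' @param p_0 Reference pressure (Pa).
#' @param p_collapse Collapse pressure (Pa), must be below `p_0`.
#' @param rho Blood density (kg/m^3).
#' @param c_0 Equilibrium pulse wave velocity (m/s).
#' @return Dimensionless exponent `b`.
#' @export
b_from_collapse <- function(p_0, p_collapse, rho, c_0) {
  den <- p_0 - p_collapse
  if (den <= 0) stop("requires p_0 > p_collapse")
  2 * rho * c_0^2 / den
}

#' Pulse wave velocity from wall stiffness
#'
#' `c_0 = sqrt(E'h / (2 rho a_0))` with `E' = E/(1 - sigma^2)` the
#' plate-corrected Young's modulus times wall thickness.
#'
#' @param Eprime_h Wall stiffness `E'h` (Pa m).
#' @param rho Blood density (kg/m^3).
#' @param a_0 Equilibrium lumen radius (m).
#' @return PWV (m/s).
#' @export
pwv_from_stiffness <- function(Eprime_h, rho, a_0) {
  stopifnot(Eprime_h >= 0, rho > 0, a_0 > 0)
  sqrt(Eprime_h / (2 * rho * a_0))
}

#' Empirical pulse-wave-velocity versus radius relations
#'
#' Evaluates one of three published fits of equilibrium PWV against lumen
#' radius. The fits are stated with the radius in centimetres and return
#' the PWV in m/s; this function takes SI metres and converts internally.
#'
#' * `olufsen_exp`:  `c^2 = 188.7 exp(-9 a_cm) + 21.19` (m^2/s^2)
#' * `blanco_biexp`: `c^2 = 40.41 exp(-5.053 a_cm) + 19.10 exp(-0.1114 a_cm)`
#' * `reymond_power`: `c = 13.3 / (20 a_cm)^0.3` (`20 a_cm` is the lumen
#'   diameter in mm)
#'
#' @param relation `"olufsen_exp"`, `"blanco_biexp"` or `"reymond_power"`.
#' @param a Lumen radius in metres, vectorized.
#' @return PWV in m/s.
#' @export
empirical_pwv <- function(relation, a) {
  relation <- match.arg(relation,
                        c("olufsen_exp", "blanco_biexp", "reymond_power"))
  stopifnot(all(a > 0))
  a_cm <- a * 100
  switch(relation,
    olufsen_exp = sqrt(188.7 * exp(-9 * a_cm) + 21.19),
    blanco_biexp = sqrt(40.41 * exp(-5.053 * a_cm) +
                          19.10 * exp(-0.1114 * a_cm)),
    reymond_power = 13.3 / (20 * a_cm)^0.3)
}

#' @rdname units_pa
#' @name units_pa
#' @title Pressure unit conversion
#' @description Fixed conversion 1 mmHg = 133.322 Pa, used at I/O
#'   boundaries; all internal computation is SI.
#' @param x Value(s) to convert.
#' @return Converted value(s).
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname units_pa
#' @export
Pa_to_mmHg <- function(x) x / 133.322
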