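#' Harmonic spectrum of a periodic signal
#'
#' Container for the two-sided Fourier representation of a real T-periodic
#' quantity, storing only the non-negative harmonics `n = 0..N` with the
#' convention `x(t) = sum_{n=-N}^{N} X_n exp(i w_n t)`, `w_n = 2 pi n / T`,
#' and `X_{-n} = Conj(X_n)`.
#'
#' @param amplitudes Complex vector of amplitudes `X_0..X_N` (length `N + 1`).
#' @param period Period `T` in seconds.
#' @param quantity Tag for the carried quantity, `"pressure"` (Pa),
#'   `"flow"` (m^3/s) or `"generic"`.
#' @return An object of class `harmonic_spectrum`.
#' @export
harmonic_spectrum <- function(amplitudes, period, quantity = "generic") {
  stopifnot(is.numeric(period), length(period) == 1L, period > 0,
            length(amplitudes) >= 1L)
  amplitudes <- as.complex(amplitudes)
  structure(
    list(amplitudes = amplitudes,
         period = period,
         n_max = length(amplitudes) - 1L,
         quantity = quantity),
    class = "harmonic_spectrum")
}

#' @export
print.harmonic_spectrum <- function(x, ...) {
  cat(sprintf("<harmonic_spectrum> %s, T = %g s, N = %d harmonics\n",
              x$quantity, x$period, x$n_max))
  cat(sprintf("  X_0 = %.6g, max |X_n>0| = %.6g\n",
              Re(x$amplitudes[1L]),
              if (x$n_max > 0L) max(Mod(x$amplitudes[-1L])) else 0))
  invisible(x)
}

#' Angular frequencies of a spectrum
#' @param spectrum A [harmonic_spectrum()].
#' @return Numeric vector `w_n = 2 pi n / T` for `n = 0..N`.
#' @export
harmonic_frequencies <- function(spectrum) {
  2 * pi * (0:spectrum$n_max) / spectrum$period
}

#' Decompose one period of a real signal into harmonic amplitudes
#'
#' Computes `X_n = (1/T) int_0^T x(t) exp(-i w_n t) dt` by the discrete
#' Fourier transform of uniform samples covering exactly one period (the
#' end point `t = T` is excluded, being identical to `t = 0`).
#'
#' @param values Real samples on a uniform grid `t_j = j T / M`,
#'   `j = 0..M-1`.
#' @param period Period `T` in seconds.
#' @param n_max Number of harmonics `N` to retain. Defaults to the smallest
#'   `N` capturing 99.99% of the oscillatory energy, capped at
#'   `floor((M - 2) / 2)`.
#' @param times Optional sample instants; if supplied they must be a uniform
#'   grid starting at 0 with step `T / M` (checked, non-uniform grids are
#'   rejected).
#' @param quantity Quantity tag, see [harmonic_spectrum()].
#' @return A [harmonic_spectrum()].
#' @export
fourier_decompose <- function(values, period, n_max = NULL, times = NULL,
                              quantity = "generic") {
  stopifnot(is.numeric(values), length(values) >= 4L, period > 0)
  m <- length(values)
  if (!is.null(times)) {
    stopifnot(length(times) == m)
    dt <- diff(times)
    if (max(abs(dt - dt[1L])) > 1e-9 * mean(abs(dt)))
      stop("non-uniform sampling: the discrete transform requires a uniform grid")
    if (abs(times[1L]) > 1e-12 * period ||
        abs((times[m] + dt[1L]) - (times[1L] + period)) > 1e-6 * period)
      stop("samples must cover exactly one period [0, T), end point excluded")
  }
  coef <- stats::fft(values) / m
  n_cap <- (m - 2L) %/% 2L
  if (is.null(n_max)) {
    full <- harmonic_spectrum(coef[seq_len(n_cap + 1L)], period, quantity)
    n_max <- tryCatch(energy_count(full, 0.9999), error = function(e) 1L)
  }
  if (n_max > n_cap)
    stop(sprintf(paste0("n_max = %d too large for %d samples: harmonics above ",
                        "%d would be aliased (need >= 2*N + 2 samples)"),
                 n_max, m, n_cap))
  harmonic_spectrum(coef[seq_len(n_max + 1L)], period, quantity)
}

#' Reconstruct the time-domain signal from a harmonic spectrum
#'
#' Evaluates `x(t) = X_0 + 2 Re sum_{n=1}^{N} X_n exp(i w_n t)`, the inverse
#' of [fourier_decompose()] under the conjugate-symmetry convention.
#'
#' @param spectrum A [harmonic_spectrum()], or a bare complex vector
#'   `X_0..X_N` together with `period`.
#' @param times Sample instants (seconds), any values.
#' @param period Period, only needed when `spectrum` is a bare vector.
#' @return Real signal values at `times`.
#' @export
fourier_reconstruct <- function(spectrum, times, period = NULL) {
  if (inherits(spectrum, "harmonic_spectrum")) {
    x <- spectrum$amplitudes
    period <- spectrum$period
  } else {
    stopifnot(!is.null(period))
    x <- as.complex(spectrum)
  }
  n <- length(x) - 1L
  out <- rep(Re(x[1L]), length(times))
  if (n > 0L) {
    e <- exp(outer(times, 2i * pi * (1:n) / period))
    out <- out + 2 * Re(as.vector(e %*% x[-1L]))
  }
  out
}

#' Harmonics needed to capture a fraction of the pulse energy
#'
#' Returns the smallest `N*` with
#' `sum_{n=1}^{N*} |X_n|^2 >= fraction * sum_{n=1}^{N} |X_n|^2`.
#' The zeroth (mean) component is excluded from both sums, so the count
#' reflects the oscillatory pulse energy only.
#'
#' @param spectrum A [harmonic_spectrum()].
#' @param fraction Energy fraction in (0, 1).
#' @return Integer harmonic count.
#' @export
energy_count <- function(spectrum, fraction = 0.95) {
  stopifnot(fraction > 0, fraction < 1)
  e <- Mod(spectrum$amplitudes[-1L])^2
  if (length(e) == 0L || sum(e) == 0)
    stop("spectrum has no nonzero oscillatory component")
  which(cumsum(e) >= fraction * sum(e))[1L]
}

#' Mean-square (Parseval) energy of a spectrum
#'
#' Mean of `x(t)^2` over one period, computed in the frequency domain as
#' `X_0^2 + 2 sum_{n>=1} |X_n|^2`.
#'
#' @param spectrum A [harmonic_spectrum()].
#' @return Scalar mean-square value.
#' @export
spectrum_mean_square <- function(spectrum) {
  x <- spectrum$amplitudes
  Re(x[1L])^2 + 2 * sum(Mod(x[-1L])^2)
}
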