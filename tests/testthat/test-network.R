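test_that("matched uniform pipe carries a pure forward wave", {
  net <- fixture_network("single_pipe", n_harmonics = 16)
  sol <- solve_linear(net, 16)
  expect_lt(sol$residual, 1e-7)
  for (n in c(1, 8, 16)) {
    sh <- sol$harmonics[[n + 1]][["pipe"]]
    backward <- Mod(sol$P_hat[n + 1, 1] - sh$Z_in * sol$Q_hat[n + 1, 1])
    expect_lt(backward / Mod(sol$P_hat[n + 1, 1]), 1e-10)
  }
})

test_that("the linear solution scales exactly with the inlet amplitude", {
  net <- fixture_network("bifurcation", n_harmonics = 12)
  sol <- solve_linear(net, 12)
  net2 <- net
  net2$inlet$spectrum$amplitudes <- 2.5 * net$inlet$spectrum$amplitudes
  sol2 <- solve_linear(net2, 12)
  expect_equal(sol2$P_hat, 2.5 * sol$P_hat, tolerance = 1e-12)
  expect_equal(sol2$Q_hat, 2.5 * sol$Q_hat, tolerance = 1e-12)
})

test_that("junction rows enforce mass and pressure continuity in time", {
  for (fx in c("bifurcation", "merging")) {
    net <- fixture_network(fx, n_harmonics = 24)
    sol <- solve_linear(net, 24)
    tt <- seq(0, 1, length.out = 128)[-128]
    if (fx == "bifurcation") {
      wp <- evaluate_waveform(sol, "parent", 0.2, tt)
      w1 <- evaluate_waveform(sol, "d1", 0, tt)
      w2 <- evaluate_waveform(sol, "d2", 0, tt)
      expect_lt(max(abs(wp$q - w1$q - w2$q)) / max(abs(wp$q)), 1e-8)
      expect_lt(max(abs(wp$p - w1$p)) / max(abs(wp$p)), 1e-8)
      expect_lt(max(abs(wp$p - w2$p)) / max(abs(wp$p)), 1e-8)
    } else {
      wv1 <- evaluate_waveform(sol, "v1", 0.15, tt)
      wv2 <- evaluate_waveform(sol, "v2", 0.15, tt)
      wb <- evaluate_waveform(sol, "basilar", 0, tt)
      expect_lt(max(abs(wv1$q + wv2$q - wb$q)) / max(abs(wb$q)), 1e-8)
      expect_lt(max(abs(wv1$p - wb$p)) / max(abs(wb$p)), 1e-8)
      expect_lt(max(abs(wv2$p - wv1$p)) / max(abs(wv1$p)), 1e-8)
    }
  }
})

test_that("an admittance-matched bifurcation produces no reflection", {
  # two daughters each with half the parent's admittance A/(rho c)
  a_p <- 0.005; a_d <- a_p / sqrt(2); c0 <- 5
  # small viscosity keeps the steady flow split determinate; the harmonic
  # rows stay lossless through the inviscid friction mode
  props <- fluid_properties(1040, 4e-6)
  m <- 256L
  q_in <- 1e-6 * cos(2 * pi * (0:(m - 1)) / m)
  segs <- list(
    vessel_segment("parent", 0.3, a_p, element_length = 0.05, pwv = c0),
    vessel_segment("d1", 0.2, a_d, element_length = 0.05, pwv = c0),
    vessel_segment("d2", 0.2, a_d, element_length = 0.05, pwv = c0))
  net <- network_model(
    segments = segs,
    junctions = list(list(parents = "parent", daughters = c("d1", "d2"))),
    inlet = list(segment = "parent", kind = "flow_forward",
                 spectrum = fourier_decompose(q_in, 1, n_max = 2,
                                              quantity = "flow")),
    outlets = list(d1 = list(model = "non_reflecting"),
                   d2 = list(model = "non_reflecting")),
    fluid = props, gamma_mode = "inviscid")
  sol <- solve_linear(net, 2)
  Zp <- 1040 * c0 / (pi * a_p^2)
  backward <- Mod(sol$P_hat[2, "parent"] - Zp * sol$Q_hat[2, "parent"])
  expect_lt(backward / Mod(sol$P_hat[2, "parent"]), 1e-10)
  # oracle: R = (Y_p - sum Y_d)/(Y_p + sum Y_d) = 0 for this geometry
  Yp <- 1 / Zp; Yd <- pi * a_d^2 / (1040 * c0)
  expect_equal((Yp - 2 * Yd) / (Yp + 2 * Yd), 0, tolerance = 1e-12)
})

test_that("outlet impedances have the printed limits", {
  wk <- list(model = "windkessel3", R1 = 1e7, R2 = 5e7, C = 1e-9)
  expect_equal(pulsefd:::outlet_impedance(wk, 0), 6e7 + 0i)
  expect_equal(Mod(pulsefd:::outlet_impedance(wk, 1e9)), 1e7,
               tolerance = 1e-4)
  expect_equal(pulsefd:::outlet_zero_resistance(wk), 6e7)
})

test_that("non-reflecting outlets absorb the incident wave energy", {
  net <- fixture_network("single_pipe", n_harmonics = 32)
  sol <- solve_linear(net, 32)
  # backward amplitude at outlet: C_b = (P - Z Q)/2 evaluated at x = L
  for (n in c(1, 10, 30)) {
    sh <- sol$harmonics[[n + 1]][["pipe"]]
    v <- sh$T_full %*% c(sol$P_hat[n + 1, 1], sol$Q_hat[n + 1, 1])
    cf <- (v[1] + sh$Z_out * v[2]) / 2
    cb <- (v[1] - sh$Z_out * v[2]) / 2
    expect_lt(Mod(cb)^2 / Mod(cf)^2, 1e-6)    # reflected energy fraction
  }
})

test_that("Murray's law splits flows by the radius power", {
  expect_equal(murray_split(1, c(0.003, 0.003)), c(0.5, 0.5))
  expect_equal(murray_split(9, c(0.004, 0.002), xi = 3), c(8, 1))
  expect_equal(sum(murray_split(0.7, c(1, 2, 3) * 1e-3, xi = 2.76)), 0.7)
  # murray zeroth closure on the bifurcation fixture
  net <- fixture_network("bifurcation", n_harmonics = 8)
  net$zeroth <- list(closure = "murray", xi = 3,
                     inlet_mean_pressure = mmHg_to_Pa(90), p_out = 0)
  sol <- solve_linear(net, 8)
  expect_equal(unname(Re(sol$Q_hat[1, "d1"])),
               unname(Re(sol$Q_hat[1, "parent"])) / 2, tolerance = 1e-12)
  expect_equal(unname(Re(sol$P_hat[1, "parent"])), mmHg_to_Pa(90))
})

test_that("a very short intermediate segment leaves the solution unchanged", {
  props <- fluid_properties(1040, 4e-6)
  m <- 256L
  q_in <- 1e-6 * (1 + cos(2 * pi * (0:(m - 1)) / m))
  mk <- function(with_stub) {
    segs <- list(vessel_segment("s1", 0.3, 0.004, element_length = 0.05,
                                pwv = 5))
    juncs <- list()
    last <- "s1"
    if (with_stub) {
      segs <- c(segs, list(vessel_segment("stub", 1e-7, 0.004,
                                          element_length = 1e-7, pwv = 5)))
      juncs <- list(list(parents = "s1", daughters = "stub"))
      last <- "stub"
    }
    outlets <- stats::setNames(list(list(model = "resistance", R_out = 5e8,
                                         p_out = 0)), last)
    network_model(segs, juncs,
                  inlet = list(segment = "s1", kind = "flow_full",
                               spectrum = fourier_decompose(q_in, 1,
                                                            n_max = 4,
                                                            quantity = "flow")),
                  outlets = outlets, fluid = props, gamma_mode = 4)
  }
  sol_a <- solve_linear(mk(FALSE), 4)
  sol_b <- solve_linear(mk(TRUE), 4)
  expect_equal(sol_b$P_hat[, "s1"], sol_a$P_hat[, "s1"], tolerance = 1e-6)
  expect_equal(sol_b$Q_hat[, "s1"], sol_a$Q_hat[, "s1"], tolerance = 1e-6)
})

test_that("ill-posed networks are rejected with diagnostics", {
  seg <- vessel_segment("s1", 0.3, 0.004, element_length = 0.05, pwv = 5)
  sp <- harmonic_spectrum(c(0i, 1e-6 + 0i), 1, "flow")
  expect_error(network_model(list(seg),
                             inlet = list(segment = "s1", kind = "flow_full",
                                          spectrum = sp),
                             outlets = list()),
               "without outlet")
  expect_error(network_model(list(seg),
                             junctions = list(list(parents = "s1",
                                                   daughters = "ghost")),
                             inlet = list(segment = "s1", kind = "flow_full",
                                          spectrum = sp),
                             outlets = list()),
               "unknown segment")
})
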