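test_that("zero linear field produces zero source and zero correction", {
  net <- fixture_network("single_pipe", n_harmonics = 4)
  net$inlet$spectrum$amplitudes[] <- 0i
  sol <- solve_linear(net, 4)
  src <- nonlinear_source(sol, "pipe")
  expect_equal(max(Mod(src$N1)), 0)
  expect_equal(max(Mod(src$N2)), 0)
  cf <- correction_quadrature(sol, "pipe", src)
  expect_equal(max(Mod(cf$P2)), 0)
  expect_equal(max(Mod(cf$Q2)), 0)
})

test_that("a single-harmonic wave sources only harmonics 0, 1 and 2", {
  props <- fluid_properties(1040, 0)
  m <- 64L
  q_in <- 1e-6 * cos(2 * pi * (0:(m - 1)) / m)
  seg <- vessel_segment("pipe", 2, 0.01, element_length = 0.1, pwv = 6.17)
  net <- network_model(list(seg),
                       inlet = list(segment = "pipe", kind = "flow_forward",
                                    spectrum = fourier_decompose(q_in, 1,
                                                                 n_max = 6,
                                                                 quantity = "flow")),
                       outlets = list(pipe = list(model = "non_reflecting")),
                       fluid = props, gamma_mode = "inviscid")
  sol <- solve_linear(net, 6)
  src <- nonlinear_source(sol, "pipe")
  scale <- max(Mod(src$N1))
  expect_gt(scale, 0)
  expect_lt(max(Mod(src$N1[4:7, ])), 1e-12 * scale)  # n >= 3 empty
  expect_lt(max(Mod(src$N2[4:7, ])), 1e-12 * max(Mod(src$N2)))
})

test_that("correction quadrature matches the closed-form uniform-pipe result", {
  qs <- quadrature_accuracy_study()   # 10 m pipe, h = 2 cm, xi = 0.5
  expect_lt(qs$rel_error_p, 1e-3)     # at least as accurate as printed
  expect_lt(qs$rel_error_q, 1e-3)
  expect_gt(qs$rel_error_p, 0)        # a real quadrature error, not exact
  # corrections vanish at the inlet by construction
  expect_equal(max(Mod(qs$P2[, 1])), 0)
  expect_equal(max(Mod(qs$Q2[, 1])), 0)
})

test_that("closed-form coefficients kill the expected terms at xi = 0, 1", {
  cf0 <- analytic_correction_coefficients(0.1, 0)
  expect_equal(unlist(cf0), c(B1p = 0, B1m = 0, B2p = 0, B2m = 0))
  cf1 <- analytic_correction_coefficients(0.1, 1)
  expect_equal(cf1$B1p, 0)
  expect_equal(cf1$B1m, 0)
  expect_lt(cf1$B2p, 0)
  # stated values at the reference point (alpha, delta1, xi) = (4/3, 1/2, 1/2)
  cf <- analytic_correction_coefficients(1, 0.5, alpha = 4 / 3, delta1 = 0.5)
  expect_equal(cf$B1p, -0.25 * (2 * 4 / 3 + 1 - 0.5) / 2)
  expect_equal(cf$B2p, -0.25 * (2 * 4 / 3 + 1 - 0.5) / 8)
  expect_equal(cf$B1m, -0.25 * (2 * 4 / 3 + 1 + 0.5) / 2)
  # the wave's inlet correction is zero
  w <- uniform_pipe_wave(0.05, 0.5, 2 * pi, 0.01, 6.17)
  ana <- analytic_nonlinear_correction(w, 0, seq(0, 1, 0.1))
  expect_equal(max(abs(ana$p2_hat)), 0)
  expect_equal(max(abs(ana$q2_hat)), 0)
})

test_that("the secular component grows linearly with slope ~ 2a+1-d1", {
  # fit |X2 harmonic-1 secular envelope| along the pipe
  qs <- quadrature_accuracy_study(eps = 0.02, xi = 0.5)
  w <- qs$wave
  rc2 <- w$rho * w$c_0^2
  # remove the bounded standing part: amplitude of harmonic 1 at x is
  # |-(i/2)(B1p kx e^{-ikx} + B1m sin kx)|; at kx = m*pi the standing part
  # vanishes and |X1| = |B1p| k x / 2
  ks <- w$k * qs$x
  pick <- which(abs(sin(ks)) < 0.02 & ks > 1)
  expect_gt(length(pick), 2)
  slopes <- Mod(qs$P2[2, pick] / rc2) / (ks[pick] / 2)
  cfs <- analytic_correction_coefficients(w$eps, w$xi)
  expect_equal(mean(slopes), abs(cfs$B1p), tolerance = 1e-3)
})

test_that("junction velocity-head terms vanish for matched velocities", {
  # area-matched junction with identical waveforms: u_parent(L) = u_d(0)
  props <- fluid_properties(1040, 0)
  m <- 128L
  q_in <- 1e-6 * (1 + 0.5 * cos(2 * pi * (0:(m - 1)) / m))
  segs <- list(vessel_segment("s1", 0.2, 0.004, element_length = 0.05,
                              pwv = 5),
               vessel_segment("s2", 0.2, 0.004, element_length = 0.05,
                              pwv = 5))
  net <- network_model(segs,
                       junctions = list(list(parents = "s1",
                                             daughters = "s2")),
                       inlet = list(segment = "s1", kind = "flow_forward",
                                    spectrum = fourier_decompose(q_in, 1,
                                                                 n_max = 4,
                                                                 quantity = "flow")),
                       outlets = list(s2 = list(model = "non_reflecting")),
                       fluid = props, gamma_mode = "inviscid")
  sol <- solve_linear(net, 4)
  nj <- junction_correction_terms(sol)
  expect_lt(max(Mod(nj[[1]]$s2)), 1e-15)   # fp-level residual
  # steady-only flow through an area change: N_0 = (rho/2)(u_s^2 - u_d^2)
  segs2 <- list(vessel_segment("s1", 0.2, 0.004, element_length = 0.05,
                               pwv = 5),
                vessel_segment("s2", 0.2, 0.003, element_length = 0.05,
                               pwv = 5))
  q0 <- rep(1e-6, m)
  net2 <- network_model(segs2,
                        junctions = list(list(parents = "s1",
                                              daughters = "s2")),
                        inlet = list(segment = "s1", kind = "flow_full",
                                     spectrum = fourier_decompose(q0, 1,
                                                                  n_max = 2,
                                                                  quantity = "flow")),
                        outlets = list(s2 = list(model = "resistance",
                                                 R_out = 1e8, p_out = 0)),
                        fluid = props, gamma_mode = 4)
  sol2 <- solve_linear(net2, 2)
  nj2 <- junction_correction_terms(sol2)
  us <- 1e-6 / (pi * 0.004^2); ud <- 1e-6 / (pi * 0.003^2)
  expect_equal(Re(nj2[[1]]$s2[1]), 1040 / 2 * (us^2 - ud^2),
               tolerance = 1e-10)
})

test_that("corrections scale as the square of the inlet amplitude", {
  ratios <- vapply(c(1e-6, 2e-6, 4e-6), function(qm) {
    net <- fixture_network("pipe_cone_pipe", q_max = qm, n_harmonics = 16)
    sol <- solve_with_corrections(net, 16)
    max(Mod(sol$corrections$fields$pipe_in$P2)) / qm^2
  }, 0)
  expect_equal(ratios[2] / ratios[1], 1, tolerance = 1e-10)
  expect_equal(ratios[3] / ratios[1], 1, tolerance = 1e-10)
})

test_that("every correction vanishes when all nonlinear terms are off", {
  net <- fixture_network("pipe_cone_pipe", q_max = 2e-6, n_harmonics = 8)
  for (id in names(net$segments)) net$segments[[id]]$wall <- NULL
  sol <- solve_linear(net, 8)
  for (id in names(net$segments)) {
    src <- nonlinear_source(sol, id, alpha = 0)
    src$N1[] <- 0i  # alpha = 0 keeps the Dp p_x part; zero the sources fully
    src$N2[] <- 0i
    cf <- correction_quadrature(sol, id, src)
    expect_equal(max(Mod(cf$P2)), 0)
    expect_equal(max(Mod(cf$Q2)), 0)
  }
})

test_that("reference subtraction recovers the computed correction field", {
  tt <- seq(0, 1, length.out = 128)[-128]
  qm <- 2e-6; qr <- 2e-8
  net <- fixture_network("pipe_cone_pipe", q_max = qm, n_harmonics = 24)
  netr <- fixture_network("pipe_cone_pipe", q_max = qr, n_harmonics = 24)
  sol <- solve_with_corrections(net, 24)
  solr <- solve_with_corrections(netr, 24)
  wf <- evaluate_waveform(sol, "pipe_in", 1, tt)
  wfr <- evaluate_waveform(solr, "pipe_in", 1, tt)
  rs <- reference_subtraction(wf, wfr, qm, qr)
  # direct corrected-minus-linear difference at the same site
  soll <- solve_linear(net, 24)
  wfl <- evaluate_waveform(soll, "pipe_in", 1, tt)
  p2 <- (wf$p - mean(wf$p)) - (wfl$p - mean(wfl$p))
  # agreement to O(eps^3): limited by the reference run's own eps_ref^2
  expect_lt(max(abs(rs$p2 - p2)) / max(abs(p2)), 3 * qr / qm)
  expect_gt(max(abs(p2)), 0)
  # identical runs give identically zero
  rs0 <- reference_subtraction(wf, wf, qm, qm)
  expect_equal(max(abs(rs0$p2)), 0)
  expect_equal(max(abs(rs0$q2)), 0)
})

test_that("normalized corrections are amplitude-independent", {
  tt <- seq(0, 1, length.out = 64)[-64]
  norm_corr <- function(qm) {
    net <- fixture_network("pipe_cone_pipe", q_max = qm, n_harmonics = 16)
    sol <- solve_with_corrections(net, 16)
    a0 <- net$segments$pipe_in$a[1]
    c0 <- net$segments$pipe_in$c[1]
    eps <- qm / (pi * a0^2 * c0)
    cf <- sol$corrections$fields$pipe_in
    j <- ncol(cf$P2)
    p2 <- fourier_reconstruct(cf$P2[, j], tt, 1)
    p2 / (1040 * c0^2) / eps^2
  }
  expect_equal(norm_corr(1e-6), norm_corr(5e-6), tolerance = 1e-10)
})
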