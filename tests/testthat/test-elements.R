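props <- blood()

test_that("uniform transmission matrix has the closed-form structure", {
  k <- 0.8 + 0i; Z <- 3e7 + 0i
  expect_equal(uniform_transmission(k, Z, 0), diag(2) + 0i)
  Tq <- uniform_transmission(k, Z, (pi / 2) / Re(k))
  expect_equal(Tq, matrix(c(0i, -1i / Z, -1i * Z, 0i), 2, 2),
               tolerance = 1e-12)
  for (x in c(0.1, 0.5, 2)) {
    Tm <- uniform_transmission(0.7 - 0.02i, 2e7 + 5e5i, x)
    expect_equal(Tm[1, 1] * Tm[2, 2] - Tm[1, 2] * Tm[2, 1], 1 + 0i,
                 tolerance = 1e-12)
  }
  expect_error(uniform_transmission(k, 0 + 0i, 1), "impedance")
})

test_that("degenerate cone reduces to the uniform matrix entry-by-entry", {
  a <- 0.004; c0 <- 5; om <- 2 * pi * 3; h <- 0.07
  Tc <- conic_element_transmission(a, a, h, om, props, c0)
  phi <- viscous_factor(a, om, props$nu)
  Tu <- uniform_transmission(wavenumber(om, c0, phi),
                             props$rho * c0 * phi / (pi * a^2), h)
  expect_equal(Tc, Tu, tolerance = 1e-14)
})

test_that("segment products obey composition and group properties", {
  seg1 <- vessel_segment("u1", 0.5, 0.004, element_length = 0.5, pwv = 5)
  seg5 <- vessel_segment("u5", 0.5, 0.004, element_length = 0.1, pwv = 5)
  om <- 2 * pi * 4
  T1 <- segment_transmission(seg1, om, props)$T_full
  T5 <- segment_transmission(seg5, om, props)$T_full
  expect_equal(T1, T5, tolerance = 1e-12)
  # composition: every node matrix equals the element matrix times the
  # previous node matrix
  sh <- segment_transmission(seg5, om, props)
  phi <- viscous_factor(0.004, om, props$nu)
  Te <- conic_element_transmission(0.004, 0.004, 0.1, om, props, 5)
  for (j in 1:5)
    expect_equal(sh$T_nodes[, , j + 1], Te %*% sh$T_nodes[, , j],
                 tolerance = 1e-12)
  # reversed traversal: the adjugate (det = 1) undoes the segment matrix
  Tb <- segment_transmission(seg1, om, props)$T_full
  inv <- matrix(c(Tb[2, 2], -Tb[2, 1], -Tb[1, 2], Tb[1, 1]), 2, 2) /
    (Tb[1, 1] * Tb[2, 2] - Tb[1, 2] * Tb[2, 1])
  prod <- inv %*% Tb
  expect_equal(prod[1, 1], 1 + 0i, tolerance = 1e-12)
  expect_equal(prod[2, 2], 1 + 0i, tolerance = 1e-12)
  expect_lt(Mod(prod[1, 2]) / Mod(Tb[1, 2]), 1e-12)
  expect_lt(Mod(prod[2, 1]) / Mod(Tb[2, 1]), 1e-12)
})

test_that("conic product converges to the ODE reference on the carotid cone", {
  fine <- carotid_cone_segment(h = 0.005)
  coarse <- carotid_cone_segment(h = 0.019)
  for (n in c(1, 3, 5)) {
    om <- 2 * pi * n
    To <- ode_transmission(fine, om, props, tol = 1e-10)
    ef <- max(Mod(segment_transmission(fine, om, props)$T_full - To))
    ec <- max(Mod(segment_transmission(coarse, om, props)$T_full - To))
    expect_lt(ef, ec)               # finer mesh strictly better
    expect_lt(ef / max(Mod(To)), 1e-3)
  }
  # observed order >= 2 in h (Richardson between h and h/2)
  om <- 2 * pi * 2
  To <- ode_transmission(fine, om, props, tol = 1e-11)
  e1 <- max(Mod(segment_transmission(carotid_cone_segment(0.0188), om,
                                     props)$T_full - To))
  e2 <- max(Mod(segment_transmission(carotid_cone_segment(0.0094), om,
                                     props)$T_full - To))
  expect_gt(e1 / e2, 3.2)           # ratio 4 for exact second order
})

test_that("a conic element with constant wave speed is exact", {
  # with c and phi constant along the cone the closed-form element is the
  # exact solution, so one element matches the ODE reference to its tol
  om <- 2 * pi * 2; c0 <- 8
  iprops <- fluid_properties(1040, 0)
  seg <- vessel_segment("c", 0.08, 0.004, 0.003, element_length = 0.08,
                        pwv = c0)
  ref <- ode_transmission(seg, om, iprops, tol = 1e-12)
  Tc <- segment_transmission(seg, om, iprops)$T_full
  expect_lt(max(Mod(Tc - ref)) / max(Mod(ref)), 1e-9)
})

test_that("steady transmission reproduces the Poiseuille drop", {
  a <- 0.004; L <- 0.5
  seg <- vessel_segment("u", L, a, element_length = 0.05, pwv = 5)
  T0 <- zeroth_transmission(seg, props$mu)
  expect_equal(Re(T0[1, 2]), -8 * props$mu * L / (pi * a^4) / pi * pi,
               tolerance = 1e-10)
  expect_equal(Re(T0[1, 2]), -8 * pi * props$mu * L / (pi * a^2)^2,
               tolerance = 1e-12)
  expect_equal(zeroth_transmission(seg, 0), diag(2) + 0i)
  # cone: trapezoid on nodes vs closed-form integral of 1/a(x)^4, with
  # second-order convergence in the node spacing
  a1 <- 0.004; a2 <- 0.002
  ax <- (a2 - a1) / 0.1
  exact <- 8 * pi * props$mu * (a2^-3 - a1^-3) / (-3 * ax) / pi^2
  errs <- vapply(c(1e-3, 5e-4), function(h) {
    cone <- vessel_segment("c", 0.1, a1, a2, element_length = h, pwv = 5)
    abs(-Re(zeroth_transmission(cone, props$mu)[1, 2]) - exact)
  }, 0)
  expect_lt(errs[1] / exact, 1e-3)
  expect_gt(errs[1] / errs[2], 3.5)
})

test_that("ODE integrator matches the closed form on a uniform segment", {
  seg <- vessel_segment("u", 0.4, 0.005, element_length = 0.4, pwv = 6)
  om <- 2 * pi * 5
  To <- ode_transmission(seg, om, props, tol = 1e-11)
  Tc <- segment_transmission(seg, om, props)$T_full
  expect_equal(To, Tc, tolerance = 1e-7)
  # inviscid flow preserves det T = 1 along the integration
  iprops <- fluid_properties(1040, 0)
  Ti <- ode_transmission(carotid_cone_segment(), om, iprops, tol = 1e-11)
  expect_equal(Ti[1, 1] * Ti[2, 2] - Ti[1, 2] * Ti[2, 1], 1 + 0i,
               tolerance = 1e-8)
})

test_that("reflection and transmission coefficients behave physically", {
  seg <- vessel_segment("u", 0.3, 0.004, element_length = 0.1, pwv = 5)
  om <- 2 * pi * 2
  rt <- reflection_transmission(seg, om, props)
  phi <- viscous_factor(0.004, om, props$nu)
  expect_lt(Mod(rt$R), 1e-12)       # matched uniform pipe: no reflection
  expect_equal(rt$S, exp(-1i * wavenumber(om, 5, phi) * 0.3),
               tolerance = 1e-10)
  # carotid cone: conic vs ODE error decreases with h for first 5 harmonics
  for (n in c(1, 5)) {
    omn <- 2 * pi * n
    ro <- reflection_transmission(carotid_cone_segment(0.005), omn, props,
                                  method = "ode")
    ef <- Mod(reflection_transmission(carotid_cone_segment(0.005), omn,
                                      props)$R - ro$R)
    ec <- Mod(reflection_transmission(carotid_cone_segment(0.019), omn,
                                      props)$R - ro$R)
    expect_lt(ef, ec)
    expect_lt(ef, 1e-3)
  }
  # inviscid power balance |R|^2 + |S|^2 (Y_R/Y_L) = 1
  iprops <- fluid_properties(1040, 0)
  cone <- vessel_segment("c", 0.094, 6.75e-3 / 2, 3.5e-3 / 2,
                         element_length = 0.002, pwv = 7)
  rt <- reflection_transmission(cone, 2 * pi * 3, iprops, method = "ode",
                                tol = 1e-11)
  YL <- pi * (6.75e-3 / 2)^2 / (1040 * 7)
  YR <- pi * (3.5e-3 / 2)^2 / (1040 * 7)
  expect_equal(Mod(rt$R)^2 + Mod(rt$S)^2 * YR / YL, 1, tolerance = 1e-8)
})

test_that("segment discretization follows the ceiling rule", {
  seg <- vessel_segment("c", 0.094, 0.003, 0.002, element_length = 0.02,
                        pwv = 5)
  expect_identical(seg$n_elements, 5L)         # ceiling(9.4/2)
  expect_equal(unique(round(seg$h, 12)), 0.094 / 5)
  expect_equal(seg$a[1], 0.003)
  expect_equal(seg$a[6], 0.002)
  expect_true(all(diff(seg$a) < 0))
  # interpolation options stay within the end radii
  for (ip in c("radius", "area", "exponential")) {
    s <- vessel_segment("s", 0.1, 0.004, 0.002, element_length = 0.01,
                        interpolation = ip, pwv = 5)
    expect_true(all(s$a <= 0.004 + 1e-15 & s$a >= 0.002 - 1e-15))
  }
})
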