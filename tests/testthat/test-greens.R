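test_that("gradient torque quadrature reproduces the closed form", {
  for (t0 in c(pi / 8, pi / 4, 3 * pi / 8)) for (zt in c(0.5, 1, 2)) {
    m <- medium_params(Gamma = 1, eta = zt^2, K = 1, g = 1)
    d <- defect_config(+1/2, t0)
    p <- activity_profile("linear", alpha0 = 0, alphag = 1)
    w <- core_vorticity(d, p, m)
    expect_equal(w$omega, omega_plus_gradient(1, t0, m),
                 tolerance = 1e-4)
  }
  # trivial zero at theta0 = 0, and the physical-units form
  expect_equal(core_vorticity(defect_config(+1/2, 0),
                              activity_profile("linear", 0, 1))$omega, 0,
               tolerance = 1e-10)
  m2 <- medium_params(Gamma = 1, eta = 4)
  expect_equal(omega_plus_gradient(1, pi / 4, m2, units = "physical"),
               (3 * pi / 4) * 2 / 4)
  expect_equal(omega_plus_gradient(2, pi / 4,
                                   medium_params(eta = 4)) ,
               omega_plus_gradient(1, pi / 4, medium_params()),
               tolerance = 1e-12)          # linear in alphag, inverse in zeta
})

test_that("uniform activity self-propels the +1/2 defect at pi/(4 zeta)", {
  m <- unit_medium()
  d <- defect_config(+1/2, 0)
  p <- activity_profile("uniform", alpha0 = 1)
  vfull <- core_velocity(d, p, m, "full_projection")
  expect_equal(vfull$v, c(pi / 4, 0), tolerance = 1e-6)
  vnone <- core_velocity(d, p, m, "none")
  expect_equal(vnone$v, c(pi / 2, 0), tolerance = 1e-6)
  # velocity is along the polarization for any theta0
  d2 <- defect_config(+1/2, 0.6)
  v2 <- core_velocity(d2, p, m, "full_projection")
  expect_close(v2$v, (pi / 4) * polarization(d2), 1e-6)
})

test_that("a constant gradient does not propel the +1/2 defect", {
  m <- unit_medium()
  d <- defect_config(+1/2, pi / 5)
  vs <- lapply(c(0, 1, 5), function(ag)
    core_velocity(d, activity_profile("linear", alpha0 = 1, alphag = ag),
                  m, "uniform_term_only")$v)
  expect_close(vs[[2]] - vs[[1]], 0, 1e-7)
  expect_close(vs[[3]] - vs[[1]], 0, 1e-7)
  expect_close(vs[[1]], (pi / 4) * polarization(d), 1e-6)
})

test_that("core vorticity ignores curl-free force perturbations", {
  m <- unit_medium()
  d <- defect_config(+1/2, pi / 4)
  p <- activity_profile("linear", alpha0 = 0.5, alphag = 1)
  base <- core_vorticity(d, p, m)$omega
  set.seed(42)
  for (k in 1:3) {
    coef <- stats::rnorm(7)
    pert <- core_vorticity(d, p, m, extra_force = poly_grad_force(coef))
    expect_equal(pert$omega, base, tolerance = 1e-7)
  }
})

test_that("-1/2 defect in a constant gradient has no velocity or rotation", {
  m <- unit_medium()
  for (t0 in c(0, 0.4, 2.0)) {
    d <- defect_config(-1/2, t0)
    p <- activity_profile("linear", alpha0 = 1, alphag = 1)
    expect_lt(sqrt(sum(core_velocity(d, p, m, "none")$v^2)), 1e-8)
    expect_lt(abs(core_vorticity(d, p, m)$omega), 1e-8)
  }
})

test_that("interfacial pressure closed form behaves as printed", {
  g <- list(x = c(1, 2), y = c(0, 0))
  p <- activity_profile("linear", alpha0 = 0, alphag = 1.7)
  # cos(2 theta0) = 0: identically zero
  p0 <- pressure_field(defect_config(+1/2, pi / 4), p, g,
                       "interfacial_plus_linear")
  expect_close(p0$value, 0, 1e-14)
  # L-independent difference along the x axis equals alphag * (2 - 1)
  p1 <- pressure_field(defect_config(+1/2, 0), p, g,
                       "interfacial_plus_linear")
  expect_equal(p1$value[2] - p1$value[1], 1.7, tolerance = 1e-12)
})

test_that("closed-form pressure satisfies the Poisson equation", {
  d <- defect_config(+1/2, pi / 7)
  p <- activity_profile("linear", alpha0 = 0.8, alphag = 1.3)
  err <- vapply(c(81, 161), function(n) {
    g <- make_grid("rectangle", L = 3, resolution = n)
    h <- g$spacing
    pf <- pressure_field(d, p, g, "bulk_plus_linear")$value +
      pressure_field(d, p, g, "interfacial_plus_linear")$value
    P <- matrix(pf, n, n)
    lap <- (P[3:n, 2:(n - 1)] + P[1:(n - 2), 2:(n - 1)] +
            P[2:(n - 1), 3:n] + P[2:(n - 1), 1:(n - 2)] -
            4 * P[2:(n - 1), 2:(n - 1)]) / h^2
    pts <- grid_points(g)
    dv <- matrix(nematicdefects:::div_active_force(d, p, pts$x, pts$y),
                 n, n)[2:(n - 1), 2:(n - 1)]
    r <- matrix(pts$r, n, n)[2:(n - 1), 2:(n - 1)]
    max(abs(lap - dv)[r > 0.8 & r < 2.5])
  }, numeric(1))
  expect_gt(log2(err[1] / err[2]), 1.7)    # second order in spacing
})

test_that("numeric pressure solve satisfies its discrete equations", {
  d <- defect_config(+1/2, 0.5)
  p <- activity_profile("linear", alpha0 = 1, alphag = 1)
  n <- 41
  g <- make_grid("rectangle", L = 3, resolution = n)
  expect_error(pressure_field(d, p, g, "numeric"), "r_core")
  pn <- pressure_field(d, p, g, "numeric", r_core = 0.5)
  lam <- attr(pn, "compatibility")
  h <- g$spacing
  P <- matrix(pn$value, n, n)
  lap <- (P[3:n, 2:(n - 1)] + P[1:(n - 2), 2:(n - 1)] +
          P[2:(n - 1), 3:n] + P[2:(n - 1), 1:(n - 2)] -
          4 * P[2:(n - 1), 2:(n - 1)]) / h^2
  rhs <- matrix(nematicdefects:::div_force_numeric(d, p, g, 0.5),
                n, n)[2:(n - 1), 2:(n - 1)]
  expect_lt(max(abs(lap + lam - rhs)), 1e-9)
})

test_that("unsupported pressure handling is rejected explicitly", {
  d <- defect_config(+1/2, 0)
  ps <- activity_profile("step", alpha0 = 1, dalpha = 1, x_v = 1)
  expect_error(core_velocity(d, ps, unit_medium(), "full_projection"),
               "not supported")
  expect_error(core_velocity(d, activity_profile("step", 1, dalpha = 1,
                                                 x_v = -0.5),
                             unit_medium(), "none"), "x_v")
  expect_error(pressure_field(defect_config(-1/2), ps, list(x = 1, y = 1),
                              "bulk_plus_linear"), "\\+1/2")
})
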