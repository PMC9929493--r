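test_that("polarization rate rotates counter-clockwise at the charge-scaled rate", {
  # q = +1/2, omega = 1, e = (1, 0): rate (0, 1)
  expect_equal(polarization_rate(+1/2, 1, c(1, 0)), c(0, 1))
  # q = -1/2 rotates 3x slower at equal vorticity
  rp <- polarization_rate(+1/2, 0.7, c(0.6, 0.8))
  rm <- polarization_rate(-1/2, 0.7, c(0.6, 0.8))
  expect_equal(sqrt(sum(rp^2)) / sqrt(sum(rm^2)), 3, tolerance = 1e-12)
  expect_equal(polarization_rate(+1/2, 0, c(0, 1)), c(0, 0))
  # rate is orthogonal to e (norm preserved to integrator order)
  expect_equal(sum(rp * c(0.6, 0.8)), 0)
})

test_that("the -1/2 polarization relaxes exactly 3x slower under equal vorticity", {
  # integrate de/dt = polarization_rate(q, omega(t), e) for a prescribed
  # vorticity signal and compare accumulated rotation angles
  omega_t <- function(t) 0.5 + 0.3 * sin(t)
  for (tol in 1) {
    ang <- sapply(c(+1/2, -1/2), function(q) {
      rhs <- function(t, y, p) list(polarization_rate(q, omega_t(t), y))
      out <- deSolve::ode(c(1, 0), seq(0, 2, length.out = 51), rhs, NULL,
                          rtol = 1e-10, atol = 1e-12)
      e <- out[nrow(out), 2:3]
      expect_equal(sum(e^2), 1, tolerance = 1e-8)   # norm conservation
      atan2(e[2], e[1])
    })
    expect_equal(as.numeric(ang[1] / ang[2]), 3, tolerance = 1e-6)
  }
})

test_that("unit polarization is conserved along integrated orientations", {
  cur <- test_curves(+1/2)
  ser <- integrate_orientation(defect_config(+1/2, 1.1), x_v = 0.3,
                               alpha0 = -1, t_span = c(0, 100),
                               n_steps = 1000, curves = cur)
  expect_lt(max(abs(ser$e_x^2 + ser$e_y^2 - 1)), 1e-8)
})

test_that("+1/2 orientation converges to the wall-normal fixed points", {
  cur <- test_curves(+1/2)
  init <- seq(0.15, pi - 0.15, length.out = 8)
  for (a0 in c(-1, 1)) {
    finals <- sapply(init, function(t0) {
      ser <- integrate_orientation(defect_config(+1/2, t0), x_v = 0.3,
                                   alpha0 = a0, t_span = c(0, 600),
                                   n_steps = 50, curves = cur)
      tail(ser$theta0, 1)
    })
    target <- if (a0 < 0) pi / 2 else 0      # 2 theta0 = pi (ext), 0 (con)
    # fold into [0, pi) and compare to the predicted stable root
    folded <- abs(((finals + pi / 2) %% pi) - pi / 2)
    expect_true(all(abs(folded - target) < 1e-3 |
                    abs(folded - (pi - target)) < 1e-3))
    rep <- stationary_orientations(+1/2, 0.3, a0)
    expect_equal(rep$theta0[rep$stable], target, tolerance = 1e-12)
  }
})

test_that("-1/2 extensile orientation relaxes to theta0 = 0 near the wall", {
  cur <- test_curves(-1/2)
  finals <- sapply(c(-1, -0.4, 0.5, 1.2), function(t0) {
    ser <- integrate_orientation(defect_config(-1/2, t0), x_v = 0.3,
                                 alpha0 = -1, t_span = c(0, 4000),
                                 n_steps = 50, curves = cur)
    tail(ser$theta0, 1)
  })
  folded <- abs(((finals + pi / 2) %% pi) - pi / 2)
  expect_true(all(folded < 1e-3))
  rep <- stationary_orientations(-1/2, 0.3, alpha0 = -1)
  expect_equal(rep$theta0[rep$stable], 0)
  # contractile flips the stable root to 2 theta0 = pi
  repc <- stationary_orientations(-1/2, 0.3, alpha0 = 1)
  expect_equal(repc$theta0[repc$stable], pi / 2)
  # far from the wall the torque dies: no-torque report
  far <- stationary_orientations(+1/2, 25, alpha0 = 1)
  expect_true(attr(far, "no_torque"))
})

test_that("an unstable root is a genuine (drifting only slowly) fixed point", {
  cur <- test_curves(+1/2)
  # the root is unstable, so round-off seeds exponential escape; on short
  # horizons the orientation stays put to integrator drift
  ser <- integrate_orientation(defect_config(+1/2, pi / 2), x_v = 0.3,
                               alpha0 = 1, t_span = c(0, 10), n_steps = 20,
                               curves = cur)
  expect_lt(max(abs(ser$theta0 - pi / 2)), 1e-6)
})

test_that("+1/2 head-on approach decelerates monotonically at the interface", {
  m <- unit_medium()
  d0 <- defect_config(+1/2, 0)
  speeds <- sapply(c(2, 1, 0.5, 0.1), function(xv)
    sqrt(sum(interface_kinematics(d0, xv, alpha0 = 1, medium = m)$v^2)))
  expect_true(all(diff(speeds) < 0))
  cur <- test_curves(+1/2, need_v = TRUE)
  tr <- integrate_trajectory(d0, 2, alpha0 = 1, t_span = c(0, 30),
                             curves = cur)
  expect_true(all(diff(tr$x_v) < 0))               # moves into the wall
  expect_true(all(diff(abs(tr$v_x)) < 1e-10))      # and slows down
  expect_true(isTRUE(attr(tr, "truncated")) || tail(tr$x_v, 1) > 0)
})

test_that("-1/2 defects with the stable orientation are attracted to the wall", {
  cur <- test_curves(-1/2, need_v = TRUE)
  tr <- integrate_trajectory(defect_config(-1/2, 0), 1, alpha0 = -1,
                             t_span = c(0, 30), curves = cur)
  expect_true(all(tr$v_x >= 0))
  expect_lt(tail(tr$x_v, 1), 1)
})

test_that("without an activity jump the trajectory is free streaming", {
  cur <- test_curves(+1/2, need_v = TRUE)
  d <- defect_config(+1/2, 0.2)
  tr <- integrate_trajectory(d, 3, alpha0 = -1, dalpha = 0,
                             t_span = c(0, 2), curves = cur)
  expect_close(tr$theta0, 0.2, 1e-10)              # no torque
  fit <- stats::lm(x_v ~ time, data = tr)
  expect_lt(max(abs(stats::residuals(fit))), 1e-8) # x_v linear in t
})
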