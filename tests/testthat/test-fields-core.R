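test_that("medium parameters expose the derived scales", {
  m <- medium_params(Gamma = 4, eta = 1, K = 2, g = 8, gamma_rot = 2)
  expect_equal(dissipation_length(m), 0.5)
  expect_equal(coherence_length(m), 0.5)
  expect_equal(zeta(m), 1)
  expect_equal(relaxation_time(m), 0.25)
  expect_error(medium_params(Gamma = 0), "> 0")
  expect_error(medium_params(eta = -1), "> 0")
})

test_that("defect texture matches the quasi-static parametrization", {
  g <- list(x = c(1, 0, 0), y = c(0, 1, 1))
  # +1/2, theta0 = 0 at (1, 0): phi = 0
  qp <- q_tensor(defect_config(+1/2), g)
  expect_equal(c(qp$Qxx[1], qp$Qxy[1]), c(1, 0))
  # -1/2, theta0 = 0 at (0, 1): phi = pi/2 -> (cos(-pi/2), sin(-pi/2))
  qm <- q_tensor(defect_config(-1/2), g)
  expect_equal(c(qm$Qxx[2], qm$Qxy[2]), c(0, -1))
  # +1/2, theta0 = pi/8 at (0, 1): angle 3 pi / 4
  q8 <- q_tensor(defect_config(+1/2, pi / 8), g)
  expect_equal(c(q8$Qxx[3], q8$Qxy[3]), c(cos(3 * pi / 4), sin(3 * pi / 4)))
})

test_that("texture amplitude is uniform off the core", {
  set.seed(11)
  pts <- list(x = stats::runif(300, -3, 3), y = stats::runif(300, -3, 3))
  for (q in c(+1/2, -1/2)) for (t0 in c(0, 0.3, 2.2)) {
    qt <- q_tensor(defect_config(q, t0), pts)
    expect_close(qt$Qxx^2 + qt$Qxy^2, 1, tol = 1e-12)
  }
  # general amplitude scales as S0/2
  qt <- q_tensor(defect_config(+1/2, 0.4, S0 = 1), pts)
  expect_close(qt$Qxx^2 + qt$Qxy^2, 0.25, tol = 1e-12)
})

test_that("core node without exclusion radius is rejected, masked with it", {
  g <- make_grid("rectangle", L = 1, resolution = 9)   # odd: contains origin
  d <- defect_config(+1/2)
  expect_error(q_tensor(d, g), "core")
  qt <- q_tensor(d, g, r_core = 0.3)
  expect_true(anyNA(qt$Qxx))
  expect_false(anyNA(qt$Qxx[grid_points(g)$r >= 0.3]))
})

test_that("polarization follows the defect symmetry", {
  expect_equal(polarization(defect_config(+1/2, 0)), c(1, 0))
  expect_close(polarization(defect_config(+1/2, pi / 4)), c(0, 1), 1e-15)
  expect_close(polarization(defect_config(-1/2, 3 * pi / 4)), c(0, 1), 1e-15)
  # unit norm for arbitrary theta0
  for (t0 in seq(0, 2 * pi, length.out = 7))
    for (q in c(+1/2, -1/2))
      expect_equal(sum(polarization(defect_config(q, t0))^2), 1)
})

test_that("+1/2 polarization equals the normalized Q divergence at the core", {
  h <- 1e-6
  for (t0 in c(0, pi / 5, 1.9)) {
    d <- defect_config(+1/2, t0)
    # centred FD of div Q on a small probe circle around the core
    probe <- function(x, y) {
      gx <- list(x = c(x + h, x - h, x, x), y = c(y, y, y + h, y - h))
      qt <- q_tensor(d, gx)
      c((qt$Qxx[1] - qt$Qxx[2]) / (2 * h) + (qt$Qxy[3] - qt$Qxy[4]) / (2 * h),
        (qt$Qxy[1] - qt$Qxy[2]) / (2 * h) - (qt$Qxx[3] - qt$Qxx[4]) / (2 * h))
    }
    dv <- probe(0.2, 0.15)
    expect_close(dv / sqrt(sum(dv^2)), polarization(d), 1e-6)
  }
})

test_that("perp is the 90-degree clockwise rotation", {
  expect_equal(perp(c(1, 0)), c(0, -1))
  expect_equal(perp(c(0, 1)), c(1, 0))
  v <- c(0.6, 0.8)
  expect_equal(perp(perp(v)), -v)
})

test_that("activity profiles evaluate exactly, with midpoint step", {
  expect_equal(activity_at(activity_profile("linear", 1, alphag = 2), 3), 7)
  st <- activity_profile("step", alpha0 = 1, dalpha = 1, x_v = 0)
  expect_equal(activity_at(st, c(-1, 1, 0)), c(1, 0, 0.5))
  expect_equal(st$alpha1, 0)
  un <- activity_profile("uniform", alpha0 = 2.5)
  expect_equal(activity_at(un, c(-5, 0, 17)), rep(2.5, 3))
})

test_that("closed-form active force matches the tabulated cases", {
  m <- unit_medium()
  # +1/2 linear, theta0 = 0 at (1, 0): interfacial force = alphag rhat
  d <- defect_config(+1/2, 0)
  p <- activity_profile("linear", alpha0 = 0, alphag = 1.5)
  f <- active_force(d, p, list(x = 1, y = 0))
  expect_close(c(f$F_I$Fx, f$F_I$Fy), c(1.5, 0), 1e-14)
  # bulk gradient part at (0, 1) with alpha0 = 0: alphag * x / r * e+ = 0
  f01 <- active_force(d, p, list(x = 0, y = 1))
  expect_close(c(f01$F_B$Fx, f01$F_B$Fy), c(0, 0), 1e-14)
  # step profile: interfacial part is a line measure, never grid-sampled
  ps <- activity_profile("step", alpha0 = 1, dalpha = 1, x_v = 0.5)
  fs <- active_force(d, ps, list(x = c(0.5, 1), y = c(0.3, 0)))
  expect_s3_class(fs$F_I, "line_measure")
  expect_equal(fs$F_I$x_at, 0.5)
  dens <- fs$F_I$density(0)
  expect_close(as.numeric(dens), c(-1, 0), 1e-14)   # -dalpha (Qxx, Qxy)
  # bulk force on the low-activity side vanishes for an active/passive jump
  expect_equal(fs$F_B$Fx[2], 0)
})

test_that("-1/2 linear-gradient force integrates to zero over centred discs", {
  d <- defect_config(-1/2, 0.7)
  p <- activity_profile("linear", alpha0 = 1, alphag = 2)
  nr <- 200; nphi <- 256
  for (R in c(1, 2)) {
    r <- (seq_len(nr) - 0.5) * (R / nr)
    phi <- 2 * pi * (seq_len(nphi) - 0.5) / nphi
    pts <- expand.grid(r = r, phi = phi)
    f <- active_force(d, p, list(x = pts$r * cos(pts$phi),
                                 y = pts$r * sin(pts$phi)))
    w <- pts$r * (R / nr) * (2 * pi / nphi)      # polar area element
    Fx <- sum((f$F_I$Fx + f$F_B$Fx) * w)
    Fy <- sum((f$F_I$Fy + f$F_B$Fy) * w)
    expect_close(c(Fx, Fy), 0, 1e-10)
  }
})

test_that("numeric force converges to the closed form at second order", {
  d <- defect_config(+1/2, pi / 7)
  p <- activity_profile("linear", alpha0 = 0.8, alphag = 1.3)
  err <- vapply(c(41, 81, 161), function(n) {
    g <- make_grid("rectangle", L = 3, resolution = n)
    fn <- active_force(d, p, g, "numeric", r_core = 1e-9)
    fc <- active_force(d, p, g, "closed_form", r_core = 1e-9)
    ann <- grid_points(g)$r > 0.5 & grid_points(g)$r < 2
    max(abs(fn$F_I$Fx - fc$F_I$Fx)[ann],
        abs(fn$F_B$Fx - fc$F_B$Fx)[ann],
        abs(fn$F_B$Fy - fc$F_B$Fy)[ann], na.rm = TRUE)
  }, numeric(1))
  orders <- log2(err[-3] / err[-1])
  expect_true(all(orders > 1.7))
})

test_that("bulk potential is minimized at amplitude 2", {
  for (g in c(0.5, 1, 7)) {
    S0 <- equilibrium_amplitude(g)
    expect_equal(S0, 2, tolerance = 1e-8)
    expect_equal(bulk_potential(S0, g), 0, tolerance = 1e-12)
    expect_equal(bulk_potential(0, g), g / 4)
  }
})
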