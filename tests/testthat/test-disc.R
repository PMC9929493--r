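omega_circle <- function(sol, frac = 0.5) {
  i <- which.min(abs(sol$r - frac * max(sol$r)))
  sol$omega[i, ]
}

test_that("disc solution satisfies no-slip and incompressibility", {
  prob <- disc_problem(2, defect_config(+1/2, -pi / 4),
                       activity_profile("linear", alpha0 = 0.5, alphag = 1),
                       unit_medium())
  sol <- solve_disc(prob)
  expect_lt(sol$residuals$no_slip, 1e-10)
  expect_lt(sol$residuals$divergence, 1e-6)
})

test_that("pure gradient forcing gives zero core velocity (alpha0 = 0)", {
  sol <- solve_disc(disc_problem(2, defect_config(+1/2, -pi / 4),
                                 activity_profile("linear", 0, alphag = 1),
                                 unit_medium()))
  expect_lt(sqrt(sum(sol$core$u0^2)), 1e-8)
  expect_gt(abs(sol$core$omega0), 0.1)     # but finite rotation
})

test_that("solutions are linear in the activity amplitudes", {
  m <- unit_medium()
  d <- defect_config(+1/2, 0.3)
  s1 <- solve_disc(disc_problem(2, d, activity_profile("uniform", 1), m))
  s2 <- solve_disc(disc_problem(2, d, activity_profile("uniform", 2), m))
  expect_close(s2$u_x, 2 * s1$u_x, 1e-10)
  expect_close(s2$omega, 2 * s1$omega, 1e-10)
  # uniform + gradient superpose
  sg <- solve_disc(disc_problem(2, d, activity_profile("linear", 0, 1), m))
  sb <- solve_disc(disc_problem(2, d, activity_profile("linear", 1, 1), m))
  expect_close(sb$u_x, s1$u_x + sg$u_x, 1e-9)
})

test_that("uniform activity drives core flow along the polarization", {
  d <- defect_config(+1/2, 0)
  sol <- solve_disc(disc_problem(8, d, activity_profile("uniform", 1),
                                 unit_medium(), resolution = 500))
  expect_gt(sol$core$u0[1], 0.5)           # contractile: along e+ = (1, 0)
  expect_lt(abs(sol$core$u0[2]), 1e-10)
  # core vorticity reading is stable under halving the interpolation radius
  sg <- solve_disc(disc_problem(2, defect_config(+1/2, -pi / 4),
                                activity_profile("linear", 0, 1),
                                unit_medium(), resolution = 400))
  h <- sg$problem$h
  w1 <- core_flow_values(sg, 2 * h)$omega0
  w2 <- core_flow_values(sg, 4 * h)$omega0
  expect_equal(w1, w2, tolerance = 0.01)
})

test_that("core vorticity crosses over from linear-in-R to the bulk torque", {
  d <- defect_config(+1/2, -pi / 4)
  p <- activity_profile("linear", alpha0 = 0, alphag = 1)
  m <- unit_medium()
  sw <- radius_sweep(c(0.1, 0.2), d, p, m, resolution = 200)
  expect_equal(sw$omega0[2] / sw$omega0[1], 2, tolerance = 0.1)
  big <- radius_sweep(10, d, p, m, resolution = 1200)
  expect_equal(abs(big$omega0), 3 * pi / 4, tolerance = 0.05 * 3 * pi / 4)
  # theta0 = 0: no torque at any radius
  s0 <- solve_disc(disc_problem(1, defect_config(+1/2, 0), p, m))
  expect_lt(abs(s0$core$omega0), 1e-10)
})

test_that("core vorticity is grid-converged at R = ell_d", {
  d <- defect_config(+1/2, -pi / 4)
  p <- activity_profile("linear", alpha0 = 0, alphag = 1)
  w1 <- solve_disc(disc_problem(1, d, p, unit_medium(),
                                resolution = 320))$core$omega0
  w2 <- solve_disc(disc_problem(1, d, p, unit_medium(),
                                resolution = 640))$core$omega0
  expect_equal(w1, w2, tolerance = 0.02)
})

test_that("vortex multiplets in the disc match the friction-limit counts", {
  m <- unit_medium()
  p <- activity_profile("linear", alpha0 = 0, alphag = 1)
  s4 <- solve_disc(disc_problem(4, defect_config(+1/2, 0), p, m,
                                n_phi = 96))
  expect_equal(count_sign_domains(omega_circle(s4))$count, 4)
  s8 <- solve_disc(disc_problem(4, defect_config(-1/2, 0), p, m,
                                n_phi = 96))
  expect_equal(count_sign_domains(omega_circle(s8))$count, 8)
  s1 <- solve_disc(disc_problem(4, defect_config(+1/2, -pi / 4), p, m,
                                n_phi = 96))
  expect_equal(count_sign_domains(omega_circle(s1))$count, 1)
})

test_that("problem validation enforces geometry and profile support", {
  expect_error(disc_problem(-1), "R must be")
  expect_error(disc_problem(1, profile = activity_profile("step", 1,
                                                          dalpha = 1,
                                                          x_v = 0.5)),
               "uniform and linear")
  expect_error(disc_problem(1, r_c = 2), "r_c")
  expect_warning(disc_problem(2, resolution = 30), "unresolved|24 nodes")
})
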