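# Screened incompressible Stokes flow in a no-slip disc, driven by the
# active force of a point defect.  Stream-function/vorticity formulation on
# a polar grid: Fourier decomposition in the angle, second-order finite
# differences in the radius.  Writing u = curl(psi zhat) (u_r = dphi psi / r,
# u_phi = -dr psi) enforces incompressibility exactly and eliminates the
# pressure; the clamped wall conditions psi(R) = psi'(R) = 0 encode no-slip.
# Each angular harmonic n satisfies the coupled radial system
#   (1 - zeta^2 L_n) omega_n = c_n,   L_n psi_n = -omega_n,
# with L_n = d^2/dr^2 + (1/r) d/dr - n^2/r^2 and c_n the harmonic of the
# curl of the active force.

#' Definition of a disc Stokes problem
#'
#' @param R disc radius (units of the coherence length).
#' @param defect a [defect_config()] (the defect sits at the disc centre).
#' @param profile an [activity_profile()] of kind `uniform` or `linear`
#'   (the forcing curl is evaluated from the analytic defect texture).
#' @param medium a [medium_params()].
#' @param resolution number of radial shells (default scales with `R` so
#'   that both the dissipation length and the core structure are resolved,
#'   with at least 24 nodes per `min(ell_d, 1)`).
#' @param n_phi number of angular nodes (default 64; the defect forcing
#'   contains harmonics up to |n| = 4 only).
#' @param r_c core radius used when reading off core flow values; must
#'   satisfy `R > r_c > 0` (default two radial spacings).  The point-defect
#'   force itself is integrable and is evaluated analytically on all
#'   shells.
#' @return Object of class `disc_problem`.
#' @export
disc_problem <- function(R, defect = defect_config(+1/2),
                         profile = activity_profile("linear", alpha0 = 0,
                                                    alphag = 1),
                         medium = medium_params(), resolution = NULL,
                         n_phi = 64, r_c = NULL) {
  if (R <= 0) stop("R must be > 0")
  if (!profile$kind %in% c("uniform", "linear"))
    stop("disc solver supports uniform and linear activity profiles")
  ld <- dissipation_length(medium) / coherence_length(medium)
  if (is.null(resolution))
    resolution <- max(160L, min(2000L, ceiling(120 * R / min(ld, 1))))
  if (resolution < ceiling(24 * R / min(ld, 1)))
    warning("resolution below 24 nodes per min(ell_d, 1); ",
            "the dissipation length may be unresolved")
  h <- R / resolution
  if (is.null(r_c)) r_c <- 2 * h
  if (!(R > r_c && r_c > 0)) stop("need R > r_c > 0")
  structure(list(R = R, defect = defect, profile = profile, medium = medium,
                 resolution = as.integer(resolution), n_phi = as.integer(n_phi),
                 r_c = r_c, h = h),
            class = "disc_problem")
}

# curl of the active force of a defect in alpha(r) = a0 + ag x, amplitude
# factor s = S0/2 (defect-centred polar coordinates; derived analytically
# from the quasi-static texture)
curl_active_force <- function(defect, profile, r, phi) {
  s <- defect$S0 / 2
  t0 <- defect$theta0
  a0 <- profile$alpha0
  ag <- if (profile$kind == "linear") profile$alphag else 0
  if (defect$charge > 0) {
    grad <- outer(1 / r, sin(2 * t0) * (1 + sin(phi)^2) +
                         cos(2 * t0) * sin(phi) * cos(phi))
    unif <- outer(1 / r^2, sin(phi - 2 * t0))
    s * (ag * grad + a0 * unif)
  } else {
    w <- 2 * phi - 2 * t0
    grad <- outer(1 / r, sin(w) * (2 - 3 * cos(phi)^2) -
                         1.5 * sin(2 * phi) * cos(w))
    unif <- outer(1 / r^2, -3 * sin(3 * phi - 2 * t0))
    s * (ag * grad + a0 * unif)
  }
}

# solve one angular harmonic; returns complex omega_n, psi_n on r = (1:N) h
solve_harmonic <- function(n, cn, r, h, zt) {
  N <- length(r)
  if (n == 0L) {
    M <- N + 1L                       # include the axis node r = 0
    iw <- function(i) i + 1L          # i = 0..N
    ip <- function(i) M + i + 1L
    i_int <- 1:(N - 1)
    ri <- r[i_int]
    trips <- rbind(
      cbind(i_int, iw(i_int - 1L), -zt^2 * (1 / h^2 - 1 / (2 * ri * h))),
      cbind(i_int, iw(i_int),       1 + zt^2 * 2 / h^2),
      cbind(i_int, iw(i_int + 1L), -zt^2 * (1 / h^2 + 1 / (2 * ri * h))),
      cbind(N - 1L + i_int, ip(i_int - 1L), 1 / h^2 - 1 / (2 * ri * h)),
      cbind(N - 1L + i_int, ip(i_int),     -2 / h^2),
      cbind(N - 1L + i_int, ip(i_int + 1L), 1 / h^2 + 1 / (2 * ri * h)),
      cbind(N - 1L + i_int, iw(i_int), 1))
    rN <- 2L * (N - 1L)
    extra <- rbind(
      c(rN + 1L, iw(0L), -3), c(rN + 1L, iw(1L), 4), c(rN + 1L, iw(2L), -1),
      c(rN + 2L, ip(0L), -3), c(rN + 2L, ip(1L), 4), c(rN + 2L, ip(2L), -1),
      c(rN + 3L, ip(N), 1),
      c(rN + 4L, ip(N), 3), c(rN + 4L, ip(N - 1L), -4), c(rN + 4L, ip(N - 2L), 1))
    A <- Matrix::sparseMatrix(i = c(trips[, 1], extra[, 1]),
                              j = c(trips[, 2], extra[, 2]),
                              x = c(trips[, 3], extra[, 3]),
                              dims = c(2L * M, 2L * M))
    b <- matrix(0, 2L * M, 2L)
    b[i_int, 1] <- Re(cn[i_int]); b[i_int, 2] <- Im(cn[i_int])
    sol <- as.matrix(Matrix::solve(A, b))
    z <- complex(real = sol[, 1], imaginary = sol[, 2])
    list(omega = z[iw(1:N)], psi = z[ip(1:N)],
         omega0 = z[iw(0L)], psi0 = z[ip(0L)])
  } else {
    iw <- function(i) i
    ip <- function(i) N + i
    i_int <- 1:(N - 1)
    ri <- r[i_int]
    trips <- rbind(
      cbind(i_int, iw(i_int),       1 + zt^2 * (2 / h^2 + n^2 / ri^2)),
      cbind(i_int, iw(i_int + 1L), -zt^2 * (1 / h^2 + 1 / (2 * ri * h))),
      cbind(N - 1L + i_int, ip(i_int),     -(2 / h^2 + n^2 / ri^2)),
      cbind(N - 1L + i_int, ip(i_int + 1L), 1 / h^2 + 1 / (2 * ri * h)),
      cbind(N - 1L + i_int, iw(i_int), 1))
    lower <- i_int[i_int > 1L]
    rl <- r[lower]
    trips <- rbind(trips,
      cbind(lower, iw(lower - 1L), -zt^2 * (1 / h^2 - 1 / (2 * rl * h))),
      cbind(N - 1L + lower, ip(lower - 1L), 1 / h^2 - 1 / (2 * rl * h)))
    rN <- 2L * (N - 1L)
    extra <- rbind(
      c(rN + 1L, ip(N), 1),
      c(rN + 2L, ip(N), 3), c(rN + 2L, ip(N - 1L), -4), c(rN + 2L, ip(N - 2L), 1))
    A <- Matrix::sparseMatrix(i = c(trips[, 1], extra[, 1]),
                              j = c(trips[, 2], extra[, 2]),
                              x = c(trips[, 3], extra[, 3]),
                              dims = c(2L * N, 2L * N))
    b <- matrix(0, 2L * N, 2L)
    b[i_int, 1] <- Re(cn[i_int]); b[i_int, 2] <- Im(cn[i_int])
    sol <- as.matrix(Matrix::solve(A, b))
    z <- complex(real = sol[, 1], imaginary = sol[, 2])
    list(omega = z[1:N], psi = z[(N + 1):(2 * N)])
  }
}

#' Solve the screened Stokes flow in a no-slip disc
#'
#' Solves `(1 - zeta^2 lap) u = F - grad p`, `div u = 0` in a disc of
#' radius `R` with `u = 0` on the wall, driven by the analytic active force
#' of the defect at the centre, and returns the velocity, vorticity and
#' stream function on the polar grid together with core values and solver
#' residuals.  See the package vignette for the discretization.
#'
#' @param problem a [disc_problem()].
#' @return Object of class `flow_solution`: list with `r`, `phi`, matrices
#'   `u_x`, `u_y`, `omega`, `psi` (rows = radial shells), `core` (list
#'   `u0`, `omega0` from [core_flow_values()]), `residuals` (max wall speed
#'   and interior divergence estimate) and the `problem`.
#' @export
solve_disc <- function(problem) {
  stopifnot(inherits(problem, "disc_problem"))
  N <- problem$resolution; h <- problem$h
  nphi <- problem$n_phi
  zt <- zeta(problem$medium)
  r <- (1:N) * h
  phi <- 2 * pi * (0:(nphi - 1)) / nphi
  C <- curl_active_force(problem$defect, problem$profile, r, phi)
  Ch <- t(stats::mvfft(t(C))) / nphi            # harmonic slots n = 0..nphi-1
  omega_h <- matrix(0 + 0i, N, nphi)
  psi_h <- matrix(0 + 0i, N, nphi)
  omega_axis <- 0
  cmax <- max(Mod(Ch))
  for (slot in 1:(nphi / 2 + 1)) {
    n <- slot - 1L
    cn <- Ch[, slot]
    if (max(Mod(cn)) < 1e-13 * cmax) next
    sol <- solve_harmonic(n, cn, r, h, zt)
    omega_h[, slot] <- sol$omega
    psi_h[, slot] <- sol$psi
    if (n == 0L) omega_axis <- Re(sol$omega0)
    if (n > 0L && n < nphi / 2) {               # conjugate mirror slot
      omega_h[, nphi - n + 1L] <- Conj(sol$omega)
      psi_h[, nphi - n + 1L] <- Conj(sol$psi)
    }
  }
  inv <- function(H) Re(t(stats::mvfft(t(H), inverse = TRUE)))
  omega <- inv(omega_h)
  psi <- inv(psi_h)
  # u_r = (1/r) dphi psi (spectral), u_phi = -dr psi (finite differences)
  ns <- c(0:(nphi / 2), -((nphi / 2 - 1):1))
  ur_h <- sweep(psi_h, 2, 1i * ns, `*`) / r
  u_r <- inv(ur_h)
  dpsi <- psi
  dpsi[2:(N - 1), ] <- (psi[3:N, ] - psi[1:(N - 2), ]) / (2 * h)
  dpsi[1, ] <- (psi[2, ] - 0) / (2 * h)          # psi ~ 0 at the axis
  dpsi[N, ] <- (3 * psi[N, ] - 4 * psi[N - 1, ] + psi[N - 2, ]) / (2 * h)
  u_phi <- -dpsi
  cphi <- matrix(cos(phi), N, nphi, byrow = TRUE)
  sphi <- matrix(sin(phi), N, nphi, byrow = TRUE)
  u_x <- u_r * cphi - u_phi * sphi
  u_y <- u_r * sphi + u_phi * cphi
  res_wall <- max(sqrt(u_x[N, ]^2 + u_y[N, ]^2))
  # interior divergence residual: (1/r) dr(r u_r) + (1/r) dphi u_phi
  div_int <- {
    i <- 2:(N - 1)
    drr <- (sweep(u_r[i + 1, ], 1, r[i + 1], `*`) -
            sweep(u_r[i - 1, ], 1, r[i - 1], `*`)) / (2 * h)
    uph_h <- t(stats::mvfft(t(u_phi))) / nphi
    dphi_u <- Re(t(stats::mvfft(t(sweep(uph_h, 2, 1i * ns, `*`)),
                                inverse = TRUE)))
    max(abs(sweep(drr + dphi_u[i, ], 1, r[i], `/`))) /
      max(abs(u_r) + abs(u_phi) + 1e-300)
  }
  sol <- structure(list(r = r, phi = phi, u_x = u_x, u_y = u_y,
                        omega = omega, psi = psi, omega_axis = omega_axis,
                        residuals = list(no_slip = res_wall,
                                         divergence = div_int),
                        problem = problem),
                   class = "flow_solution")
  sol$core <- core_flow_values(sol)
  sol
}

#' @export
print.flow_solution <- function(x, ...) {
  p <- x$problem
  cat(sprintf("Disc flow solution: R = %g, %d x %d nodes, zeta = %g\n",
              p$R, p$resolution, p$n_phi, zeta(p$medium)))
  cat(sprintf("  u(0) = (%.6g, %.6g), omega(0) = %.6g\n",
              x$core$u0[1], x$core$u0[2], x$core$omega0))
  cat(sprintf("  residuals: no-slip %.3g, divergence %.3g\n",
              x$residuals$no_slip, x$residuals$divergence))
  invisible(x)
}

#' Flow values at the defect core
#'
#' The defect self-propulsion velocity is the net active flow through the
#' core; on the discrete solution the core values are read off by averaging
#' the fields over a small circle around the centre (radial linear
#' interpolation, uniform angular average), which filters the angular
#' harmonics that vanish at the origin.
#'
#' @param solution a `flow_solution`.
#' @param interpolation_radius circle radius; at least 2 radial spacings
#'   (default 3) and at most `max(5 r_c, 5 spacings)`.
#' @return List with `u0` (velocity 2-vector) and `omega0`.
#' @export
core_flow_values <- function(solution, interpolation_radius = NULL) {
  h <- solution$problem$h
  if (is.null(interpolation_radius)) interpolation_radius <- 3 * h
  if (interpolation_radius < 2 * h)
    stop("interpolation radius must be at least 2 radial spacings")
  if (interpolation_radius > max(5 * solution$problem$r_c, 5 * h))
    stop("interpolation radius too far from the core neighbourhood")
  rr <- interpolation_radius
  i0 <- max(1L, floor(rr / h)); i1 <- i0 + 1L
  w1 <- (rr - solution$r[i0]) / h
  interp <- function(M) (1 - w1) * M[i0, ] + w1 * M[i1, ]
  list(u0 = c(mean(interp(solution$u_x)), mean(interp(solution$u_y))),
       omega0 = mean(interp(solution$omega)))
}

#' Core vorticity as a function of disc radius
#'
#' Solves the disc problem for each radius in `R_list` and tabulates the
#' core vorticity.  For radii below the dissipation length the magnitude
#' grows linearly with `R` (slope proportional to `1/eta`); for large discs
#' it saturates at the unbounded-domain gradient torque
#' [omega_plus_gradient()].
#'
#' @param R_list disc radii, ideally spanning both sides of `ell_d`.
#' @param defect,profile,medium as in [disc_problem()].
#' @param resolution,n_phi optional overrides passed to [disc_problem()].
#' @return data frame with columns `R`, `omega0`, `u0_x`, `u0_y`,
#'   `no_slip_residual`.
#' @export
radius_sweep <- function(R_list, defect = defect_config(+1/2, theta0 = -pi/4),
                         profile = activity_profile("linear", alpha0 = 0,
                                                    alphag = 1),
                         medium = medium_params(), resolution = NULL,
                         n_phi = 48) {
  rows <- lapply(R_list, function(R) {
    prob <- disc_problem(R, defect, profile, medium,
                         resolution = resolution, n_phi = n_phi)
    sol <- solve_disc(prob)
    data.frame(R = R, omega0 = sol$core$omega0,
               u0_x = sol$core$u0[1], u0_y = sol$core$u0[2],
               no_slip_residual = sol$residuals$no_slip)
  })
  do.call(rbind, rows)
}
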