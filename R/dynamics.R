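# Vorticity-driven defect dynamics near a sharp activity interface.  The
# local flow vorticity rotates the background director at rate omega/2,
# which carries the defect polarization with it; the polarization vector
# obeys  de/dt = -3^(q - 1/2) omega perp(e)  (a counter-clockwise rotation
# at rate omega for q = +1/2, and at omega/3 for q = -1/2 whose
# polarization angle is 2 theta0 / 3).  The orientation is integrated in
# the angle variable theta0, which conserves |e| = 1 exactly; the vector
# rate is exposed for completeness.

#' Rotation rate of the defect polarization
#'
#' `de/dt = -3^(-1/2 + q) omega perp(e)`: the vorticity-induced torque
#' rotates the polarization counter-clockwise at rate `omega` for the
#' +1/2 defect and at `omega / 3` for the -1/2 defect (whose polarization
#' angle is `2 theta0 / 3` while the background angle advances at
#' `omega / 2`).  The rate is orthogonal to `e`, so the norm is preserved
#' to integrator order.
#'
#' @param q defect charge (+1/2 or -1/2).
#' @param omega local flow vorticity at the core.
#' @param e current polarization (unit 2-vector).
#' @return The rate `de/dt` (2-vector).
#' @export
polarization_rate <- function(q, omega, e) {
  stopifnot(length(e) == 2L)
  -3^(-1/2 + q) * omega * perp(e)
}

# angular velocity of the background orientation theta0 at fixed wall
# distance, from the interface profile functions (dimensional units)
theta0_rate <- function(charge, x_v, theta0, alpha0, dalpha, medium, curves) {
  eta <- medium$eta
  if (charge > 0) {
    f <- curves$f_omega_plus$interp(x_v)
    -(dalpha / (4 * pi * eta)) * sin(2 * theta0) * f
  } else {
    f <- curves$f_omega_minus$interp(x_v)
    -(dalpha / (4 * pi * eta)) * sin(2 * theta0) * f
  }
}

default_curves <- function(charge, need_v = FALSE, x_max = 12) {
  xs <- c(seq(0.02, 0.3, by = 0.02), seq(0.35, 2, by = 0.05),
          seq(2.2, 6, by = 0.2), 7:12)
  xs <- xs[xs <= x_max]
  if (charge > 0) {
    out <- list(f_omega_plus = profile_curve("f_omega_plus", xs))
    if (need_v) out$f_v_plus <- profile_curve("f_v_plus", xs)
  } else {
    out <- list(f_omega_minus = profile_curve("f_omega_minus", xs))
    if (need_v) out$f_v_minus <- profile_curve("f_v_minus", xs)
  }
  out
}

#' Integrate the defect orientation at fixed wall distance
#'
#' Integrates `d theta0/dt = omega(x_v, theta0) / 2` with the torque from
#' [interface_kinematics()], holding the wall distance fixed.  The
#' orientation converges to a stable root of `sin(2 theta0) = 0`; which
#' root is stable depends on the sign of the activity jump (see
#' [stationary_orientations()]).
#'
#' @param defect a [defect_config()]; `theta0` is the initial orientation.
#' @param x_v wall distance (units of `ell_d`), held fixed.
#' @param alpha0 bulk activity (negative = extensile).
#' @param dalpha activity jump (defaults to `alpha0`, an active/passive
#'   interface).
#' @param medium a [medium_params()].
#' @param t_span integration time span `c(t0, t1)`.
#' @param n_steps number of output samples.
#' @param curves optional pre-tabulated [profile_curve()] list.
#' @return data frame of class `dynamics_series` with columns `time`,
#'   `x_v`, `theta0`, `e_x`, `e_y`, `v_x`, `v_y`, `omega`.
#' @export
integrate_orientation <- function(defect, x_v, alpha0, dalpha = alpha0,
                                  medium = medium_params(),
                                  t_span = c(0, 200), n_steps = 200,
                                  curves = NULL) {
  if (is.null(curves)) curves <- default_curves(defect$charge)
  times <- seq(t_span[1], t_span[2], length.out = n_steps + 1)
  rhs <- function(t, y, parms) {
    list(theta0_rate(defect$charge, x_v, y[1], alpha0, dalpha, medium,
                     curves))
  }
  out <- deSolve::ode(y = c(theta0 = defect$theta0), times = times,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  series_from_theta(out[, "time"], rep(x_v, nrow(out)), out[, "theta0"],
                    defect, alpha0, dalpha, medium, curves)
}

#' Integrate the coupled wall-distance and orientation dynamics
#'
#' Couples the drift towards/away from the interface,
#' `dx_v/dt = -v_x(x_v, theta0)` (the wall distance shrinks when the
#' defect moves towards the interface at `x > 0`), with the orientation
#' dynamics `d theta0/dt = omega / 2`.  Integration terminates when the
#' wall distance falls below `x_v_min` (the torque diverges at the wall
#' and the minimal model loses validity); the returned series carries a
#' `truncated` attribute in that case.
#'
#' @inheritParams integrate_orientation
#' @param x_v_init initial wall distance (> 0, units of `ell_d`).
#' @param x_v_min truncation cutoff (default 1e-3).
#' @return data frame of class `dynamics_series` (see
#'   [integrate_orientation()]).
#' @export
integrate_trajectory <- function(defect, x_v_init, alpha0, dalpha = alpha0,
                                 medium = medium_params(),
                                 t_span = c(0, 100), n_steps = 400,
                                 x_v_min = 1e-3, curves = NULL) {
  stopifnot(x_v_init > 0)
  if (is.null(curves))
    curves <- default_curves(defect$charge, need_v = TRUE,
                             x_max = max(12, x_v_init + 2))
  ld <- dissipation_length(medium)
  times <- seq(t_span[1], t_span[2], length.out = n_steps + 1)
  rhs <- function(t, y, parms) {
    xv <- max(y[1], x_v_min)
    kin <- kin_at(defect, xv, y[2], alpha0, dalpha, medium, curves)
    list(c(-kin$v[1] / ld,          # x_v measured in units of ell_d
           kin$omega / 2))
  }
  root <- function(t, y, parms) y[1] - x_v_min
  out <- deSolve::lsodar(y = c(x_v = x_v_init, theta0 = defect$theta0),
                         times = times, func = rhs, parms = NULL,
                         rootfunc = root, rtol = 1e-9, atol = 1e-11)
  truncated <- nrow(out) < length(times)
  ser <- series_from_theta(out[, "time"], out[, "x_v"], out[, "theta0"],
                           defect, alpha0, dalpha, medium, curves)
  attr(ser, "truncated") <- truncated
  ser
}

kin_at <- function(defect, x_v, theta0, alpha0, dalpha, medium, curves) {
  d <- defect; d$theta0 <- theta0
  interface_kinematics(d, x_v, alpha0, dalpha, medium, curves = curves)
}

series_from_theta <- function(time, x_v, theta0, defect, alpha0, dalpha,
                              medium, curves) {
  rows <- mapply(function(xv, t0) {
    kin <- kin_at(defect, xv, t0, alpha0, dalpha, medium, curves)
    c(kin$v, kin$omega)
  }, x_v, theta0)
  a <- if (defect$charge > 0) 2 * theta0 else 2 * theta0 / 3
  ser <- data.frame(time = time, x_v = x_v, theta0 = theta0,
                    e_x = cos(a), e_y = sin(a),
                    v_x = rows[1, ], v_y = rows[2, ], omega = rows[3, ])
  class(ser) <- c("dynamics_series", "data.frame")
  ser
}

#' Stationary orientations and their stability
#'
#' The torque on either defect is proportional to `-sin(2 theta0)`, so the
#' stationary orientations are the roots `2 theta0 = 0` and `2 theta0 =
#' pi` (mod `2 pi`).  Stability follows from the sign of
#' `d(omega)/d(theta0)` at the root (stable when negative): for the +1/2
#' defect near an active/passive interface the stable orientation is
#' `2 theta0 = pi` for extensile activity (`alpha0 < 0`, polarization
#' pointing away from the wall) and `2 theta0 = 0` for contractile
#' activity; for the -1/2 defect close to the wall (where
#' `f_omega_minus < 0`) it is `theta0 = 0` for extensile and
#' `2 theta0 = pi` for contractile activity.
#'
#' @param charge defect charge (+1/2 or -1/2).
#' @param x_v wall distance (units of `ell_d`).
#' @param alpha0 bulk activity; its sign selects the extensile or
#'   contractile regime.
#' @param dalpha activity jump (defaults to `alpha0`).
#' @param medium a [medium_params()].
#' @param torque_tol torque magnitudes below this report a no-torque
#'   result (defect effectively free, far from the wall).
#' @return Object of class `fixed_point_report`: data frame of roots
#'   `theta0` in `[0, pi)` with stability labels, plus attributes `regime`
#'   and `f_omega`.
#' @export
stationary_orientations <- function(charge, x_v, alpha0, dalpha = alpha0,
                                    medium = medium_params(),
                                    torque_tol = 1e-10) {
  f <- if (charge > 0) f_omega_plus(x_v) else f_omega_minus(x_v)
  C <- (dalpha / (4 * pi * medium$eta)) * f     # theta0dot = -C sin(2 theta0)
  regime <- if (alpha0 < 0) "extensile" else "contractile"
  if (abs(C) < torque_tol) {
    rep <- data.frame(theta0 = numeric(0), two_theta0 = numeric(0),
                      stable = logical(0))
    attr(rep, "no_torque") <- TRUE
  } else {
    roots <- c(0, pi / 2)                        # 2 theta0 = 0, pi
    # d(theta0dot)/d(theta0) = -2 C cos(2 theta0)
    stab <- -2 * C * cos(2 * roots) < 0
    rep <- data.frame(theta0 = roots, two_theta0 = 2 * roots, stable = stab)
    attr(rep, "no_torque") <- FALSE
  }
  attr(rep, "regime") <- regime
  attr(rep, "f_omega") <- f
  attr(rep, "charge") <- charge
  class(rep) <- c("fixed_point_report", "data.frame")
  rep
}

#' @export
print.fixed_point_report <- function(x, ...) {
  cat(sprintf("Stationary orientations (%s, q = %+.1f):\n",
              attr(x, "regime"), attr(x, "charge")))
  if (isTRUE(attr(x, "no_torque"))) {
    cat("  torque below tolerance: no preferred orientation\n")
  } else {
    for (i in seq_len(nrow(x)))
      cat(sprintf("  2 theta0 = %s : %s\n",
                  format(x$two_theta0[i]),
                  if (x$stable[i]) "stable" else "unstable"))
  }
  invisible(x)
}
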