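# Interface profile functions: wall-distance dependence of the defect
# kinematics near a sharp activity jump.  All four functions take the wall
# distance x_v in units of the dissipation length ell_d and are defined by
# reduced quadratures of the screened-Stokes kernel; the area integrals over
# the low-activity half plane are taken in defect-centred polar coordinates
# (region r > x_v / cos(phi)), where int_a^Inf K1 = K0(a) collapses the
# radial integral of the K1-kernel terms.

# int_a^Inf K0(t) dt, with exponential tail cutoff
k0_tail <- function(a, rel_tol = 1e-12) {
  if (a > 700) return(0)
  quad1(function(t) besselK(t, 0), a, Inf, rel_tol = rel_tol)$value
}

# shared line integrand: int dy K0(sqrt(xv^2+y^2)) xv / sqrt(xv^2+y^2)
line_k0 <- function(x_v, rel_tol = 1e-12) {
  if (x_v == 0) return(0)
  2 * quad1(function(y) {
    rv <- sqrt(x_v^2 + y^2)
    besselK(rv, 0) * x_v / rv
  }, 0, Inf, rel_tol = rel_tol)$value
}

#' Interface profile functions for a defect near a sharp activity jump
#'
#' Dimensionless wall-distance functions multiplying the kinematic
#' prefactors of a defect at distance `x_v` (in units of the dissipation
#' length) from a sharp active/passive interface, on the high-activity
#' side:
#' \describe{
#'   \item{`f_v_plus`}{self-propulsion attenuation of the +1/2 defect:
#'     `v+ = (alpha0 pi ell_d / 4 eta) f_v_plus(x_v) e+`.  Rises
#'     monotonically from 0 at the wall to 1 far away.}
#'   \item{`f_omega_plus`}{vorticity-induced torque on the +1/2 defect:
#'     `omega+ = -(dalpha / 2 pi eta) sin(2 theta0) f_omega_plus(x_v)`.
#'     Positive, increasing towards the wall, divergent as `x_v -> 0`.}
#'   \item{`f_v_minus`}{interfacial self-propulsion of the -1/2 defect
#'     along `n- = (cos 2 theta0, sin 2 theta0)`:
#'     `v- = -(dalpha ell_d / 2 pi eta) f_v_minus(x_v) n-`.  Vanishes far
#'     from the wall (the -1/2 defect is non-motile in the bulk).}
#'   \item{`f_omega_minus`}{torque on the -1/2 defect:
#'     `omega- = -(dalpha / 2 pi eta) sin(2 theta0) f_omega_minus(x_v)`.
#'     Changes sign near the wall and diverges (negatively) as
#'     `x_v -> 0`.}
#' }
#' The `f_omega` functions diverge logarithmically at the wall; values
#' requested below `div_cutoff` are returned with a warning and flagged.
#'
#' @param x_v wall distance(s) in units of `ell_d`; `>= 0` for the `f_v`
#'   functions, `> 0` for the `f_omega` functions.
#' @param rel_tol quadrature tolerance.
#' @param div_cutoff divergence cutoff for the `f_omega` functions
#'   (default 1e-3).
#' @return Numeric vector of function values.
#' @examples
#' f_v_plus(c(0, 1, 30))
#' @export
f_v_plus <- function(x_v, rel_tol = 1e-10) {
  vapply(x_v, function(xv) {
    if (xv < 0) stop("x_v must be >= 0 (defect on the high-activity side)")
    ln <- line_k0(xv, rel_tol)
    ar <- 2 * quad1(Vectorize(function(p) k0_tail(xv / cos(p), rel_tol)),
                    0, pi / 2, rel_tol = rel_tol)$value
    1 - (2 / pi^2) * (ln + ar)
  }, numeric(1))
}

#' @rdname f_v_plus
#' @export
f_omega_plus <- function(x_v, rel_tol = 1e-10, div_cutoff = 1e-3) {
  out <- vapply(x_v, function(xv) {
    if (xv <= 0) stop("x_v must be > 0 for f_omega_plus")
    ln <- 2 * quad1(function(y) besselK(sqrt(xv^2 + y^2), 1),
                    0, Inf, rel_tol = rel_tol)$value
    ar <- 2 * quad1(function(p) cos(p) * bk0_safe(xv / cos(p)),
                    0, pi / 2, rel_tol = rel_tol)$value
    ln + ar
  }, numeric(1))
  flag_divergence(out, x_v, div_cutoff, "f_omega_plus")
}

#' @rdname f_v_plus
#' @export
f_v_minus <- function(x_v, rel_tol = 1e-10) {
  vapply(x_v, function(xv) {
    if (xv < 0) stop("x_v must be >= 0 (defect on the high-activity side)")
    ln <- line_k0(xv, rel_tol)
    ar <- 2 * quad1(Vectorize(function(p)
      cos(2 * p) * k0_tail(xv / cos(p), rel_tol)),
      0, pi / 2, rel_tol = rel_tol)$value
    ln - ar
  }, numeric(1))
}

#' @rdname f_v_plus
#' @export
f_omega_minus <- function(x_v, rel_tol = 1e-10, div_cutoff = 1e-3) {
  out <- vapply(x_v, function(xv) {
    if (xv <= 0) stop("x_v must be > 0 for f_omega_minus")
    ln <- 2 * quad1(function(y) {
      rv2 <- xv^2 + y^2
      besselK(sqrt(rv2), 1) * (xv^2 - y^2) / rv2
    }, 0, Inf, rel_tol = rel_tol)$value
    ar <- 2 * quad1(function(p) cos(3 * p) * bk0_safe(xv / cos(p)),
                    0, pi / 2, rel_tol = rel_tol)$value
    ln - ar
  }, numeric(1))
  flag_divergence(out, x_v, div_cutoff, "f_omega_minus")
}

bk0_safe <- function(a) ifelse(a > 700, 0, besselK(pmin(a, 700), 0))

flag_divergence <- function(values, x_v, cutoff, name) {
  near <- x_v < cutoff
  if (any(near)) {
    warning(name, " diverges as x_v -> 0; values at x_v < ", cutoff,
            " are unreliable")
    attr(values, "divergent") <- near
  }
  values
}

#' Tabulated interface profile curve
#'
#' Evaluates one of the four interface profile functions on a grid of wall
#' distances and returns a curve object carrying the table, quadrature
#' metadata and a cubic-spline interpolator (used by the dynamics
#' integrators, which would otherwise pay a quadrature per ODE step).
#'
#' @param which one of `"f_v_plus"`, `"f_omega_plus"`, `"f_v_minus"`,
#'   `"f_omega_minus"`.
#' @param x_v strictly increasing positive wall distances (units of
#'   `ell_d`).
#' @param rel_tol quadrature tolerance.
#' @return Object of class `profile_curve` with elements `which`, `table`
#'   (data frame `x_v`, `value`, `abs_error`), `interp` (function) and
#'   `divergent` (logical flags near the wall cutoff).
#' @export
profile_curve <- function(which = c("f_v_plus", "f_omega_plus", "f_v_minus",
                                    "f_omega_minus"),
                          x_v = NULL, rel_tol = 1e-9) {
  which <- match.arg(which)
  if (is.null(x_v))
    x_v <- c(seq(0.02, 0.3, by = 0.02), seq(0.35, 2, by = 0.05),
             seq(2.2, 6, by = 0.2), 7:12)
  if (any(diff(x_v) <= 0) || any(x_v <= 0))
    stop("x_v must be strictly increasing and positive")
  f <- match.fun(which)
  vals <- suppressWarnings(f(x_v, rel_tol = rel_tol))
  tab <- data.frame(x_v = x_v, value = as.numeric(vals),
                    abs_error = rel_tol * pmax(abs(vals), 1))
  interp <- stats::splinefun(tab$x_v, tab$value, method = "natural")
  structure(list(which = which, table = tab, interp = interp,
                 rel_tol = rel_tol,
                 divergent = x_v < 1e-3),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("Profile curve %s: %d points on x_v in [%g, %g]\n",
              x$which, nrow(x$table), min(x$table$x_v), max(x$table$x_v)))
  invisible(x)
}

#' Defect kinematics near a sharp activity interface
#'
#' Assembles the dimensional self-propulsion velocity and angular velocity
#' of a defect at wall distance `x_v` (units of `ell_d`) from the interface
#' profile functions:
#' \itemize{
#'   \item +1/2: `v = (pi ell_d / 4 eta) [alpha0 - dalpha (1 - f_v_plus)] e+`
#'     (reducing to `(alpha0 pi ell_d / 4 eta) f_v_plus e+` for an
#'     active/passive interface `dalpha = alpha0`), and
#'     `omega = -(dalpha / 2 pi eta) sin(2 theta0) f_omega_plus`.
#'   \item -1/2: `v = -(dalpha ell_d / 2 pi eta) f_v_minus n-` with
#'     `n- = (cos 2 theta0, sin 2 theta0)`, and
#'     `omega = -(dalpha / 2 pi eta) sin(2 theta0) f_omega_minus`.
#' }
#' The -1/2 drift direction is `n-`, not the threefold polarization axis
#' `e-`; the torque prefactor is written with `dalpha`, which coincides
#' with the bulk activity `alpha0` for an active/passive interface (the
#' uniform part of the activity exerts no torque on its own).
#'
#' @param defect a [defect_config()].
#' @param x_v wall distance in units of `ell_d` (scalar).
#' @param alpha0 bulk activity on the defect's side.
#' @param dalpha activity jump across the interface.
#' @param medium a [medium_params()].
#' @param curves optional named list of [profile_curve()] objects
#'   (`f_v_plus`, ...) used instead of direct quadrature.
#' @return A `kinematics_result` in physical units.
#' @export
interface_kinematics <- function(defect, x_v, alpha0, dalpha = alpha0,
                                 medium = medium_params(), curves = NULL) {
  stopifnot(length(x_v) == 1L, x_v >= 0)
  ld <- dissipation_length(medium)
  eta <- medium$eta
  t0 <- defect$theta0
  ev <- function(name) {
    if (!is.null(curves[[name]])) curves[[name]]$interp(x_v)
    else suppressWarnings(match.fun(name)(max(x_v, 1e-6)))
  }
  if (defect$charge > 0) {
    fv <- if (x_v == 0 && is.null(curves)) f_v_plus(0) else ev("f_v_plus")
    v <- (pi * ld / (4 * eta)) * (alpha0 - dalpha * (1 - fv)) *
      polarization(defect)
    omega <- -(dalpha / (2 * pi * eta)) * sin(2 * t0) * ev("f_omega_plus")
  } else {
    fv <- if (x_v == 0 && is.null(curves)) f_v_minus(0) else ev("f_v_minus")
    nminus <- c(cos(2 * t0), sin(2 * t0))
    v <- -(dalpha * ld / (2 * pi * eta)) * fv * nminus
    omega <- -(dalpha / (2 * pi * eta)) * sin(2 * t0) * ev("f_omega_minus")
  }
  kin_result(v = v, omega = omega, pressure_mode = "uniform_term_only",
             units = "physical")
}
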