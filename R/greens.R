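# ---- quadrature helpers ------------------------------------------------

# adaptive 1D quadrature with diagnostics on failure
quad1 <- function(f, lower, upper, rel_tol = 1e-9, ...) {
  res <- tryCatch(
    stats::integrate(f, lower, upper, rel.tol = rel_tol,
                     subdivisions = 400L, stop.on.error = FALSE, ...),
    error = function(e) stop("quadrature failure on [", lower, ", ", upper,
                             "]: ", conditionMessage(e)))
  if (!res$message %in% c("OK", "the integral is probably divergent") &&
      res$message != "OK")
    stop("quadrature did not converge: ", res$message,
         " (abs.error = ", format(res$abs.error), ")")
  res
}

# mean over the circle of f(phi) using an nphi-point periodic midpoint rule
# (spectrally accurate for trigonometric integrands of harmonic < nphi/2)
phi_rule <- function(nphi) 2 * pi * (seq_len(nphi) - 0.5) / nphi

# core value of (1/(2 pi zeta^2)) int K0(r/zeta) F d2r for a smooth force
# Ffun(r, phi): phi vector at scalar r -> list(Fx, Fy)
kernel_core_velocity_smooth <- function(Ffun, zeta, r_max, rel_tol, nphi = 256) {
  ph <- phi_rule(nphi)
  avg <- function(r, comp) vapply(r, function(ri) {
    F <- Ffun(ri, ph); mean(F[[comp]])
  }, numeric(1))
  err <- 0
  v <- vapply(c("Fx", "Fy"), function(comp) {
    I <- quad1(function(r) r * besselK(r / zeta, 0) * avg(r, comp),
               0, r_max, rel_tol = rel_tol)
    err <<- err + I$abs.error
    I$value / zeta^2
  }, numeric(1))
  list(v = unname(v), abs_error = err / zeta^2)
}

# core vorticity of a smooth force via the gradient-of-kernel identity
#   omega = (1/(2 pi zeta^3)) int K1(r/zeta) (rhat x F) d2r
kernel_core_vorticity_smooth <- function(Ffun, zeta, r_max, rel_tol,
                                         nphi = 256) {
  ph <- phi_rule(nphi)
  avg <- function(r) vapply(r, function(ri) {
    F <- Ffun(ri, ph)
    mean(cos(ph) * F$Fy - sin(ph) * F$Fx)
  }, numeric(1))
  I <- quad1(function(r) r * besselK(r / zeta, 1) * avg(r), 0, r_max,
             rel_tol = rel_tol)
  list(omega = I$value / zeta^3, abs_error = I$abs.error / zeta^3)
}

# region integral over the half-plane x > x_v in defect-centred polar
# coordinates: int dphi int_{x_v/cos phi}^{r_max} g(r, phi) dr, with the
# outer integral adaptive over phi in (-pi/2, pi/2)
halfplane_quad <- function(g, x_v, r_max, rel_tol) {
  err <- 0
  inner <- Vectorize(function(p) {
    lo <- x_v / cos(p)
    if (lo >= r_max) return(0)
    I <- quad1(function(r) g(r, p), lo, r_max, rel_tol = rel_tol)
    err <<- err + I$abs.error
    I$value
  })
  I <- quad1(inner, -pi / 2, pi / 2, rel_tol = rel_tol)
  list(value = I$value, abs_error = I$abs.error + err)
}

# ---- kinematics result container --------------------------------------

kin_result <- function(v = c(NA_real_, NA_real_), omega = NA_real_,
                       v_I = c(0, 0), v_B = c(0, 0),
                       omega_I = NA_real_, omega_B = NA_real_,
                       pressure_mode = NA_character_, abs_error = 0,
                       units = "rescaled") {
  structure(list(v = v, omega = omega, v_I = v_I, v_B = v_B,
                 omega_I = omega_I, omega_B = omega_B,
                 pressure_mode = pressure_mode, abs_error = abs_error,
                 units = units),
            class = "kinematics_result")
}

#' @export
print.kinematics_result <- function(x, ...) {
  cat("Defect kinematics (", x$units, " units):\n", sep = "")
  if (!anyNA(x$v))
    cat(sprintf("  v     = (%.8g, %.8g)  |v| = %.8g\n", x$v[1], x$v[2],
                sqrt(sum(x$v^2))))
  if (!is.na(x$omega)) cat(sprintf("  omega = %.8g\n", x$omega))
  if (!is.na(x$pressure_mode))
    cat("  pressure mode:", x$pressure_mode, "\n")
  cat(sprintf("  quadrature error estimate: %.3g\n", x$abs_error))
  invisible(x)
}

# ---- core velocity -----------------------------------------------------

#' Defect self-propulsion velocity from the screened-Stokes Green's function
#'
#' Evaluates the net active flow through the defect core,
#' `v = (1/(2 pi zeta^2)) int K0(r/zeta) [F(r) - grad p] d^2 r`,
#' for the supported activity profiles, in rescaled units (lengths in the
#' coherence length xi, time in the nematic relaxation time tau).  The
#' quadrature is performed in defect-centred polar coordinates, where the
#' area element cancels the integrable 1/r singularity of the force; the
#' exponentially decaying kernel is truncated at `r_max` (default
#' `40 * zeta`, relative truncation error below 1e-15).  For a step profile
#' the delta-line interfacial force is reduced analytically to a 1D
#' quadrature along the interface.
#'
#' Pressure handling (`pressure_mode`):
#' \describe{
#'   \item{`"none"`}{no incompressibility correction (pure K0 kernel).}
#'   \item{`"uniform_term_only"`}{the transverse (divergence-free) projection
#'     is applied only to the uniform-`alpha0` bulk term, exactly halving
#'     its contribution; gradient/jump terms are left unprojected.  This is
#'     the prescription under which the interface profile functions
#'     [f_v_plus()] etc. are defined.}
#'   \item{`"full_projection"`}{the transverse projection evaluated in the
#'     spectral domain for the uniform term, plus subtraction of the
#'     closed-form gradient pressure for the linear profile (whose core
#'     contribution vanishes by parity).  Not available for the step
#'     profile: the pressure induced by the activity jump has no closed
#'     form and is deliberately not modelled.}
#' }
#'
#' @param defect a [defect_config()].
#' @param profile an [activity_profile()] (`step` profiles require
#'   `x_v >= 0`: the defect sits on the high-activity side).
#' @param medium a [medium_params()]; only `zeta` enters in rescaled units.
#' @param pressure_mode see Details.
#' @param rel_tol relative quadrature tolerance.
#' @param r_max kernel truncation radius (defaults to `40 * zeta`).
#' @return A `kinematics_result` with the velocity `v`, its
#'   interfacial/bulk split and quadrature error estimates.
#' @export
core_velocity <- function(defect, profile, medium = medium_params(),
                          pressure_mode = c("uniform_term_only", "none",
                                            "full_projection"),
                          rel_tol = 1e-9, r_max = NULL) {
  pressure_mode <- match.arg(pressure_mode)
  zt <- zeta(medium)
  if (is.null(r_max)) r_max <- 40 * zt
  s <- defect$S0 / 2
  a0 <- profile$alpha0
  err <- 0

  # uniform-alpha0 bulk term (full plane)
  v0 <- if (pressure_mode == "none") {
    res <- kernel_core_velocity_smooth(function(r, ph) {
      dq <- div_q(defect, r * cos(ph), r * sin(ph))
      list(Fx = a0 * dq$x, Fy = a0 * dq$y)
    }, zt, r_max, rel_tol)
    err <- err + res$abs_error
    res$v
  } else {
    pr <- uniform_projected_velocity(defect, a0, zt, rel_tol)
    err <- err + pr$abs_error
    pr$v
  }

  extra <- switch(profile$kind,
    uniform = list(v = c(0, 0), abs_error = 0),
    linear = {
      ag <- profile$alphag
      res <- kernel_core_velocity_smooth(function(r, ph) {
        x <- r * cos(ph); y <- r * sin(ph)
        dq <- div_q(defect, x, y)
        qt <- q_tensor(defect, list(x = x, y = y))
        Fx <- ag * qt$Qxx + ag * x * dq$x
        Fy <- ag * qt$Qxy + ag * x * dq$y
        if (pressure_mode == "full_projection") {
          gp <- grad_pressure_linear(defect, ag, x, y)
          Fx <- Fx - gp$x; Fy <- Fy - gp$y
        }
        list(Fx = Fx, Fy = Fy)
      }, zt, r_max, rel_tol)
      list(v = res$v, abs_error = res$abs_error)
    },
    step = {
      if (pressure_mode == "full_projection")
        stop("full_projection is not supported for the step profile: ",
             "the jump-induced pressure has no closed form; use ",
             "'uniform_term_only'")
      if (profile$x_v < 0)
        stop("step profile requires x_v >= 0 (defect on the high-activity side)")
      step_jump_velocity(defect, profile, zt, r_max, rel_tol)
    })
  err <- err + extra$abs_error
  v_B <- v0 + if (!is.null(extra$v_B)) extra$v_B else extra$v
  v_I <- if (!is.null(extra$v_I)) extra$v_I else c(0, 0)
  kin_result(v = v_B + v_I, v_I = v_I, v_B = v_B,
             pressure_mode = pressure_mode, abs_error = err)
}

# transverse-projected uniform-activity term, evaluated in the spectral
# domain: for F = s a0 e/r, Fhat = 2 pi s a0 e / k and the projection
# (I - khat khat) averages to 1/2, so v = (s a0 / 2) int_0^inf dk/(1+z^2 k^2) e.
# The -1/2 texture has zero circular average and contributes nothing.
uniform_projected_velocity <- function(defect, a0, zt, rel_tol) {
  if (defect$charge < 0 || a0 == 0)
    return(list(v = c(0, 0), abs_error = 0))
  s <- defect$S0 / 2
  I <- quad1(function(k) 1 / (1 + zt^2 * k^2), 0, Inf, rel_tol = rel_tol)
  list(v = (s * a0 / 2) * I$value * polarization(defect),
       abs_error = (s * abs(a0) / 2) * I$abs.error)
}

# gradient of the closed-form pressure of the linear-gradient force
# (interfacial + bulk gradient parts; the uniform part is handled
# spectrally).  p_I = s ag cos(2 t0) r;
# p_Bg = s ag [ cos(2 t0) ((x^2-y^2)/r + 3 r)/6 - sin(2 t0) x y/(3 r) ].
grad_pressure_linear <- function(defect, ag, x, y) {
  t0 <- defect$theta0
  s <- defect$S0 / 2
  r <- sqrt(x^2 + y^2)
  c2 <- cos(2 * t0); s2 <- sin(2 * t0)
  # d/dx, d/dy of (x^2 - y^2)/r
  dfx <- 2 * x / r - (x^2 - y^2) * x / r^3
  dfy <- -2 * y / r - (x^2 - y^2) * y / r^3
  # d/dx, d/dy of x y / r
  dgx <- y / r - x^2 * y / r^3
  dgy <- x / r - x * y^2 / r^3
  px <- s * ag * (c2 * x / r + c2 * (dfx + 3 * x / r) / 6 + s2 * dgx / 3)
  py <- s * ag * (c2 * y / r + c2 * (dfy + 3 * y / r) / 6 + s2 * dgy / 3)
  list(x = px, y = py)
}

# interfacial (delta-line) + bulk-jump velocity contributions of the step
step_jump_velocity <- function(defect, profile, zt, r_max, rel_tol) {
  s <- defect$S0 / 2
  da <- profile$dalpha; x_v <- profile$x_v
  dens <- step_line_density(defect, profile)
  err <- 0
  # line term: (1/(2 pi zeta^2)) int dy K0(r_v/zeta) dens(y)
  v_I <- vapply(1:2, function(comp) {
    I <- quad1(function(y) {
      besselK(pmax(sqrt(x_v^2 + y^2), 1e-300) / zt, 0) * dens(y)[, comp]
    }, -r_max, r_max, rel_tol = rel_tol)
    err <<- err + I$abs.error
    I$value / (2 * pi * zt^2)
  }, numeric(1))
  # bulk jump term: -dalpha H(x - x_v) s * divq over the half plane
  ang <- if (defect$charge > 0) {
    e <- polarization(defect)
    function(p) cbind(-da * s * e[1] + 0 * p, -da * s * e[2] + 0 * p)
  } else {
    t0 <- defect$theta0
    function(p) cbind(-da * s * -cos(2 * p - 2 * t0),
                      -da * s * sin(2 * p - 2 * t0))
  }
  v_B <- vapply(1:2, function(comp) {
    hq <- halfplane_quad(function(r, p) {
      besselK(r / zt, 0) * ang(p)[, comp]
    }, x_v, r_max, rel_tol)
    err <<- err + hq$abs_error
    hq$value / (2 * pi * zt^2)
  }, numeric(1))
  list(v_I = unname(v_I), v_B = unname(v_B), abs_error = err)
}

# ---- core vorticity ----------------------------------------------------

#' Flow vorticity at the defect core
#'
#' Evaluates `omega = -(1/(2 pi zeta^2)) int K0(r/zeta) (grad_perp . F) d^2 r`
#' at the defect position, in rescaled units, with the sign convention
#' `omega = dx u_y - dy u_x`.  The curl of the singular force is handled by
#' moving the derivative onto the kernel (integration by parts), giving the
#' equivalent form `omega = (1/(2 pi zeta^3)) int K1(r/zeta) (rhat x F) d^2 r`
#' which is regular for all supported profiles; the delta-line force of a
#' step profile reduces analytically to a 1D quadrature along the
#' interface.  Pressure gradients are curl-free and never contribute; a
#' smooth gradient field can be added through `extra_force` to verify this.
#'
#' @inheritParams core_velocity
#' @param extra_force optional `function(x, y)` returning a list with
#'   components `Fx`, `Fy`, added to the smooth part of the force (used to
#'   check invariance under curl-free perturbations).
#' @return A `kinematics_result` with `omega` and its interfacial/bulk
#'   split.
#' @export
core_vorticity <- function(defect, profile, medium = medium_params(),
                           rel_tol = 1e-9, r_max = NULL, extra_force = NULL) {
  zt <- zeta(medium)
  if (is.null(r_max)) r_max <- 40 * zt
  s <- defect$S0 / 2
  a0 <- profile$alpha0
  err <- 0

  smooth <- function(r, ph) {
    x <- r * cos(ph); y <- r * sin(ph)
    dq <- div_q(defect, x, y)
    Fx <- a0 * dq$x; Fy <- a0 * dq$y
    if (profile$kind == "linear") {
      qt <- q_tensor(defect, list(x = x, y = y))
      Fx <- Fx + profile$alphag * (qt$Qxx + x * dq$x)
      Fy <- Fy + profile$alphag * (qt$Qxy + x * dq$y)
    }
    if (!is.null(extra_force)) {
      ex <- extra_force(x, y)
      Fx <- Fx + ex$Fx; Fy <- Fy + ex$Fy
    }
    list(Fx = Fx, Fy = Fy)
  }
  sm <- kernel_core_vorticity_smooth(smooth, zt, r_max, rel_tol)
  err <- err + sm$abs_error
  omega_B <- sm$omega
  omega_I <- 0

  if (profile$kind == "step") {
    if (profile$x_v < 0)
      stop("step profile requires x_v >= 0")
    x_v <- profile$x_v
    dens <- step_line_density(defect, profile)
    I <- quad1(function(y) {
      rv <- pmax(sqrt(x_v^2 + y^2), 1e-300)
      d <- dens(y)
      besselK(rv / zt, 1) * (x_v * d[, 2] - y * d[, 1]) / rv
    }, -r_max, r_max, rel_tol = rel_tol)
    omega_I <- I$value / (2 * pi * zt^3)
    err <- err + I$abs.error
    # bulk jump: -dalpha H(x - x_v) s divq; (rhat x F) has a closed angular
    # factor but is integrated numerically over the half plane
    t0 <- defect$theta0
    angf <- if (defect$charge > 0)
      function(p) -profile$dalpha * s * sin(2 * t0 - p)
    else
      function(p) -profile$dalpha * s * sin(3 * p - 2 * t0)
    hq <- halfplane_quad(function(r, p) besselK(r / zt, 1) * angf(p),
                         x_v, r_max, rel_tol)
    omega_B <- omega_B + hq$value / (2 * pi * zt^3)
    err <- err + hq$abs_error
  }
  kin_result(omega = omega_I + omega_B, omega_I = omega_I,
             omega_B = omega_B, abs_error = err)
}

#' Closed-form gradient torque on a +1/2 defect
#'
#' The angular velocity acquired by a +1/2 defect in a constant activity
#' gradient: `omega+ = (3 pi / 4) alphag sin(2 theta0) / zeta` in rescaled
#' units, or `omega+ = (3 pi / 4) alphag ell_d sin(2 theta0) / eta` in
#' physical units.  It is linear in the gradient, odd in `2 theta0` and
#' scales with the dissipation length.
#'
#' @param alphag activity gradient.
#' @param theta0 background orientation (radians).
#' @param medium a [medium_params()].
#' @param units `"rescaled"` or `"physical"`.
#' @return Scalar angular velocity.
#' @export
omega_plus_gradient <- function(alphag, theta0, medium = medium_params(),
                                units = c("rescaled", "physical")) {
  units <- match.arg(units)
  if (units == "rescaled")
    (3 * pi / 4) * alphag * sin(2 * theta0) / zeta(medium)
  else
    (3 * pi / 4) * alphag * dissipation_length(medium) *
      sin(2 * theta0) / medium$eta
}

# ---- pressure fields ---------------------------------------------------

#' Pressure field enforcing incompressibility
#'
#' Closed forms for the pressure generated by the active force of a +1/2
#' defect in a linear activity profile (`which = "interfacial_plus_linear"`
#' and `"bulk_plus_linear"`), or a finite-difference Poisson solve of
#' `lap p = div F` on a rectangle grid (`which = "numeric"`).  The additive
#' constant (the `-L` system-size term of the closed forms) is dropped:
#' only pressure gradients act on the flow.  The bulk closed form includes
#' the uniform-activity contribution `p0 = s alpha0 (e+ . rhat)`, obtained
#' from the transverse projection of the `alpha0` force.
#'
#' @param defect a [defect_config()] (closed forms require charge +1/2).
#' @param profile an [activity_profile()] of kind `uniform` or `linear`.
#' @param grid evaluation grid (`numeric` requires a rectangle grid
#'   excluding the core).
#' @param which one of `"interfacial_plus_linear"`, `"bulk_plus_linear"`,
#'   `"numeric"`.
#' @param r_core core-exclusion radius for the numeric mode.
#' @return A `scalar_field` list with `grid`, `value`.
#' @export
pressure_field <- function(defect, profile, grid,
                           which = c("interfacial_plus_linear",
                                     "bulk_plus_linear", "numeric"),
                           r_core = NULL) {
  which <- match.arg(which)
  pts <- as_points(grid)
  x <- pts$x; y <- pts$y
  r <- sqrt(x^2 + y^2)
  s <- defect$S0 / 2
  t0 <- defect$theta0
  if (which != "numeric" && defect$charge < 0)
    stop("closed-form pressure is tabulated for the +1/2 defect only")
  val <- switch(which,
    interfacial_plus_linear = s * profile$alphag * cos(2 * t0) * r,
    bulk_plus_linear = {
      p0 <- s * profile$alpha0 * cos(atan2(y, x) - 2 * t0)
      # the xy term carries the sign required by lap p = div F with the
      # bulk force as implemented (see vignette)
      pg <- s * profile$alphag *
        (cos(2 * t0) * ((x^2 - y^2) / r + 3 * r) / 6 +
         sin(2 * t0) * x * y / (3 * r))
      p0 + pg
    },
    numeric = return(pressure_poisson(defect, profile, grid, r_core)))
  structure(list(grid = grid, value = val, label = "p", units = "rescaled"),
            class = "scalar_field")
}

# analytic divergence of the closed-form active force (uniform/linear):
#  +1/2: div F = s [ 2 ag cos(2 t0) / r - alpha(x) cos(phi - 2 t0) / r^2 ]
#  -1/2: div F = s [ -2 ag cos(2 phi - 2 t0) / r
#                    + 3 alpha(x) cos(3 phi - 2 t0) / r^2 ]
div_active_force <- function(defect, profile, x, y) {
  s <- defect$S0 / 2
  r <- sqrt(x^2 + y^2)
  ph <- atan2(y, x)
  alpha <- activity_at(profile, x)
  ag <- profile$alphag
  t0 <- defect$theta0
  if (defect$charge > 0)
    s * (2 * ag * cos(2 * t0) / r - alpha * cos(ph - 2 * t0) / r^2)
  else
    s * (-2 * ag * cos(2 * ph - 2 * t0) / r +
         3 * alpha * cos(3 * ph - 2 * t0) / r^2)
}

# Poisson solve with zero-normal-derivative closure.  A pure Neumann
# problem is solvable only when the total source vanishes; the defect
# force has a net flux, so the system is solved in bordered (saddle) form
# with a Lagrange multiplier lambda that absorbs the compatibility defect
# as a uniform source offset: lap p = div F - lambda, mean(p) = 0.  lambda
# is returned as attribute "compatibility" and is the constant against
# which interior residuals should be checked.
pressure_poisson <- function(defect, profile, grid, r_core) {
  if (!inherits(grid, "grid2d") || grid$domain != "rectangle")
    stop("numeric pressure requires a rectangle grid2d")
  if (is.null(r_core))
    stop("numeric pressure on a grid containing the core requires r_core")
  n <- grid$resolution; h <- grid$spacing
  rhs_all <- div_force_numeric(defect, profile, grid, r_core)
  idx <- function(i, j) (j - 1L) * n + i
  ij <- expand.grid(i = 2:(n - 1), j = 2:(n - 1))
  ki <- idx(ij$i, ij$j)
  trips <- rbind(
    cbind(ki, ki, -4 / h^2),
    cbind(ki, idx(ij$i - 1L, ij$j), 1 / h^2),
    cbind(ki, idx(ij$i + 1L, ij$j), 1 / h^2),
    cbind(ki, idx(ij$i, ij$j - 1L), 1 / h^2),
    cbind(ki, idx(ij$i, ij$j + 1L), 1 / h^2),
    cbind(ki, n * n + 1L, 1))                       # + lambda
  # boundary rows: copy the clamped inner neighbour (dp/dn = 0)
  bd <- expand.grid(i = 1:n, j = 1:n)
  bd <- bd[bd$i %in% c(1L, n) | bd$j %in% c(1L, n), ]
  kb <- idx(bd$i, bd$j)
  nb <- idx(pmin(pmax(bd$i, 2L), n - 1L), pmin(pmax(bd$j, 2L), n - 1L))
  trips <- rbind(trips, cbind(kb, kb, 1), cbind(kb, nb, -1),
                 cbind(n * n + 1L, ki, 1))          # gauge: mean over interior
  A <- Matrix::sparseMatrix(i = trips[, 1], j = trips[, 2], x = trips[, 3],
                            dims = c(n * n + 1L, n * n + 1L))
  b <- numeric(n * n + 1L)
  b[ki] <- rhs_all[ki]
  sol <- as.numeric(Matrix::solve(A, b))
  structure(list(grid = grid, value = sol[seq_len(n * n)], label = "p",
                 units = "rescaled"),
            class = "scalar_field",
            compatibility = sol[n * n + 1L])
}

# divergence of the force on a rectangle grid; analytic where tabulated,
# with the core region (r < r_core) masked to zero source
div_force_numeric <- function(defect, profile, grid, r_core) {
  pts <- grid_points(grid)
  r <- sqrt(pts$x^2 + pts$y^2)
  d <- if (defect$charge > 0 && profile$kind %in% c("uniform", "linear")) {
    div_active_force(defect, profile, pts$x, pts$y)
  } else {
    f <- active_force(defect, profile, grid, mode = "numeric",
                      r_core = r_core)
    n <- grid$resolution; h <- grid$spacing
    Fx <- matrix(f$F_I$Fx + f$F_B$Fx, n, n)
    Fy <- matrix(f$F_I$Fy + f$F_B$Fy, n, n)
    dv <- matrix(NA_real_, n, n)
    dv[2:(n - 1), 2:(n - 1)] <-
      (Fx[3:n, 2:(n - 1)] - Fx[1:(n - 2), 2:(n - 1)]) / (2 * h) +
      (Fy[2:(n - 1), 3:n] - Fy[2:(n - 1), 1:(n - 2)]) / (2 * h)
    as.vector(dv)
  }
  d[!is.finite(d) | r < r_core] <- 0
  d
}
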