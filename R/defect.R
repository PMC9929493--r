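#' Configuration of an isolated half-integer defect
#'
#' Describes a point defect of topological charge q = +1/2 or -1/2 in the
#' director field of a 2D nematic.  `theta0` is the slowly varying background
#' orientation of the director far from the core; it sets the defect
#' polarization (see [polarization()]).  The order-parameter amplitude of the
#' surrounding uniform state is `S0` (2 for the minimizer of the bulk
#' potential, see [equilibrium_amplitude()]).
#'
#' `theta0` is stored as given.  Physically it is only meaningful modulo the
#' defect symmetry: the +1/2 polarization angle 2*theta0 is pi-periodic in
#' theta0, while the -1/2 defect has three equivalent polarization axes
#' (2*pi/3 sector symmetry).
#'
#' @param charge defect charge, exactly +1/2 or -1/2.
#' @param theta0 background nematic orientation (radians).
#' @param position defect core position, length-2 numeric (defaults to the
#'   origin; all field constructors are defect-centred).
#' @param S0 uniform order-parameter amplitude (dimensionless, default 2).
#' @return An object of class `defect_config`.
#' @examples
#' d <- defect_config(+1/2, theta0 = pi / 4)
#' polarization(d)
#' @export
defect_config <- function(charge, theta0 = 0, position = c(0, 0), S0 = 2) {
  if (!isTRUE(abs(abs(charge) - 0.5) < .Machine$double.eps))
    stop("charge must be exactly +1/2 or -1/2")
  stopifnot(is.numeric(theta0), length(theta0) == 1L, is.finite(theta0),
            is.numeric(position), length(position) == 2L, S0 > 0)
  structure(list(charge = charge, theta0 = theta0,
                 position = as.numeric(position), S0 = S0),
            class = "defect_config")
}

#' @export
print.defect_config <- function(x, ...) {
  cat(sprintf("%+.1g/2 nematic defect: theta0 = %g, position = (%g, %g), S0 = %g\n",
              sign(x$charge), x$theta0, x$position[1], x$position[2], x$S0))
  cat(sprintf("  polarization e = (%.6g, %.6g)\n",
              polarization(x)[1], polarization(x)[2]))
  invisible(x)
}

#' Defect polarization vector
#'
#' The +1/2 defect is polar: its polarization is the direction of the
#' normalized divergence of the Q tensor at the core,
#' `e+ = (cos 2*theta0, sin 2*theta0)`.  The -1/2 defect is threefold
#' symmetric; its conventional polarization picks one of the three
#' equivalent axes, `e- = (cos(2*theta0/3), sin(2*theta0/3))`.
#'
#' @param defect a [defect_config()].
#' @return Unit 2-vector.
#' @export
polarization <- function(defect) {
  a <- if (defect$charge > 0) 2 * defect$theta0 else 2 * defect$theta0 / 3
  c(cos(a), sin(a))
}

#' Clockwise 90-degree rotation of a 2-vector
#'
#' Returns `(v_y, -v_x)`.  Applying it twice gives `-v`.  This is the
#' rotation entering the vorticity-induced torque on the defect
#' polarization.
#'
#' @param v numeric 2-vector.
#' @return numeric 2-vector.
#' @export
perp <- function(v) {
  stopifnot(length(v) == 2L)
  c(v[2], -v[1])
}

#' Bulk ordering potential of the Q tensor
#'
#' The local part of the de Gennes-Landau free energy density for a uniaxial
#' Q tensor `Q = S (n n - I/2)`, for which `Tr(Q^2) = S^2 / 2`:
#' `U(S) = (g/4) (1 - S^2/4)^2`.
#'
#' @param S order-parameter amplitude(s).
#' @param g ordering strength, > 0.
#' @return Potential value(s), same length as `S`.
#' @export
bulk_potential <- function(S, g = 1) {
  stopifnot(g > 0)
  (g / 4) * (1 - S^2 / 4)^2
}

#' Equilibrium order-parameter amplitude
#'
#' Finds the nonzero minimizer of the bulk ordering potential
#' [bulk_potential()] by 1D numerical minimization, polished by Newton
#' iteration on the stationarity condition.  For any `g > 0` the minimizer
#' is the uniform nematic amplitude S0 = 2.
#'
#' @param g ordering strength, > 0.
#' @return The equilibrium amplitude S0.
#' @export
equilibrium_amplitude <- function(g = 1) {
  stopifnot(g > 0)
  s <- stats::optimize(bulk_potential, interval = c(1e-6, 10), g = g,
                       tol = 1e-10)$minimum
  # Newton polish on dU/dS = -(g/4) S (1 - S^2/4)
  for (i in 1:8) {
    f  <- -(g / 4) * s * (1 - s^2 / 4)
    df <- -(g / 4) * (1 - 3 * s^2 / 4)
    s  <- s - f / df
  }
  s
}
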