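#' Parametric activity profile
#'
#' The scalar activity alpha(r) multiplying the active stress `alpha * Q`.
#' Three families are supported:
#' \describe{
#'   \item{`uniform`}{`alpha(r) = alpha0` everywhere.}
#'   \item{`linear`}{`alpha(r) = alpha0 + alphag * x`, a constant gradient
#'     along +x.}
#'   \item{`step`}{`alpha(r) = alpha0 - dalpha * H(x - x_v)`, a sharp
#'     interface at `x = x_v` separating a high-activity region
#'     (`alpha0`, containing the defect at the origin when `x_v > 0`) from a
#'     low-activity region `alpha1 = alpha0 - dalpha`.  An active/passive
#'     interface is `dalpha = alpha0`.}
#' }
#' Negative activity is extensile (pushers), positive contractile (pullers).
#'
#' @param kind one of `"uniform"`, `"linear"`, `"step"`.
#' @param alpha0 bulk activity (stress; rescaled units in all field/kinematic
#'   evaluators).
#' @param alphag activity gradient (linear profile only).
#' @param dalpha activity jump across the interface (step profile only).
#' @param x_v interface position along x (step profile only).
#' @return An object of class `activity_profile`.
#' @examples
#' activity_at(activity_profile("linear", alpha0 = 1, alphag = 2), x = 3)
#' @export
activity_profile <- function(kind = c("uniform", "linear", "step"),
                             alpha0 = 1, alphag = 0, dalpha = 0, x_v = 0) {
  kind <- match.arg(kind)
  stopifnot(is.finite(alpha0), is.finite(alphag), is.finite(dalpha),
            is.finite(x_v))
  structure(list(kind = kind, alpha0 = alpha0,
                 alphag = if (kind == "linear") alphag else 0,
                 dalpha = if (kind == "step") dalpha else 0,
                 x_v = if (kind == "step") x_v else NA_real_,
                 alpha1 = if (kind == "step") alpha0 - dalpha else NA_real_),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(switch(x$kind,
    uniform = sprintf("Uniform activity: alpha = %g\n", x$alpha0),
    linear  = sprintf("Linear activity: alpha = %g + %g x\n",
                      x$alpha0, x$alphag),
    step    = sprintf("Step activity: alpha = %g - %g H(x - %g)  (alpha1 = %g)\n",
                      x$alpha0, x$dalpha, x$x_v, x$alpha1)))
  invisible(x)
}

#' Evaluate an activity profile
#'
#' Exact pointwise evaluation of alpha(r).  On the interface line of a step
#' profile (`x == x_v` exactly) the midpoint convention `H(0) = 1/2` is
#' used, so that centred finite differencing across the interface is
#' symmetric.
#'
#' @param profile an [activity_profile()].
#' @param x,y coordinates (y is ignored; profiles vary along x only).
#' @return Numeric vector of activity values.
#' @export
activity_at <- function(profile, x, y = NULL) {
  if (!inherits(profile, "activity_profile")) stop("not an activity_profile")
  switch(profile$kind,
    uniform = rep(profile$alpha0, length(x)),
    linear  = profile$alpha0 + profile$alphag * x,
    step    = {
      h <- ifelse(x > profile$x_v, 1, ifelse(x < profile$x_v, 0, 0.5))
      profile$alpha0 - profile$dalpha * h
    },
    stop("unknown activity profile kind"))
}
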