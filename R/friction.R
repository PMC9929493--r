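# Friction-dominated limit: with viscous transport negligible the flow is
# local, Gamma u = F - grad p, and the vorticity field away from the core
# follows the curl of the active force pointwise.  Valid for alpha0 = 0
# (a pure activity gradient); both maps decay as 1/r.

#' Friction-limit vorticity maps of a defect in a constant activity gradient
#'
#' Pointwise evaluation of the vortical flow around a defect in the
#' friction-dominated limit with `alpha0 = 0`:
#' \itemize{
#'   \item +1/2 defect:
#'     `omega+ = alphag sin(2 phi) cos(2 theta0) / (2 Gamma r) +
#'       alphag sin(2 theta0) (1 + cos^2 phi) / (Gamma r)`.
#'     For small `theta0` the first term dominates and produces the
#'     fourfold (quadruple) vortex pattern; at `|theta0| = pi/4` the second
#'     term is a single-signed vortex centred on the core.
#'   \item -1/2 defect:
#'     `omega- = -alphag cos(2 theta0) (3 sin 4 phi - sin 2 phi) / (2 Gamma r)
#'       + alphag sin(2 theta0) (3 cos 4 phi - cos 2 phi) / (2 Gamma r)`,
#'     an eightfold pattern of counter-rotating vortices.
#' }
#' Both maps scale exactly as 1/r, and the `theta0` dependence is an exact
#' linear combination (weights `cos 2 theta0`, `sin 2 theta0`) of the
#' `theta0 = 0` and `theta0 = pi/4` maps.
#'
#' @param grid a [make_grid()] grid, a data frame with `x`, `y`, or a list
#'   with polar `r`, `phi`.
#' @param alphag activity gradient.
#' @param Gamma friction coefficient.
#' @param theta0 background orientation (radians).
#' @return A `scalar_field` with the vorticity values; nodes at `r = 0`
#'   are an error.
#' @export
vorticity_map_plus <- function(grid, alphag = 1, Gamma = 1, theta0 = 0) {
  pp <- map_polar(grid)
  w <- alphag * sin(2 * pp$phi) * cos(2 * theta0) / (2 * Gamma * pp$r) +
    alphag * sin(2 * theta0) * (1 + cos(pp$phi)^2) / (Gamma * pp$r)
  structure(list(grid = grid, value = w, label = "omega",
                 units = "1/time (friction limit)"),
            class = "scalar_field")
}

#' @rdname vorticity_map_plus
#' @export
vorticity_map_minus <- function(grid, alphag = 1, Gamma = 1, theta0 = 0) {
  pp <- map_polar(grid)
  w <- -alphag * cos(2 * theta0) *
         (3 * sin(4 * pp$phi) - sin(2 * pp$phi)) / (2 * Gamma * pp$r) +
       alphag * sin(2 * theta0) *
         (3 * cos(4 * pp$phi) - cos(2 * pp$phi)) / (2 * Gamma * pp$r)
  structure(list(grid = grid, value = w, label = "omega",
                 units = "1/time (friction limit)"),
            class = "scalar_field")
}

map_polar <- function(grid) {
  if (is.list(grid) && !is.null(grid$r) && !is.null(grid$phi) &&
      !inherits(grid, "grid2d"))
    pp <- data.frame(r = grid$r, phi = grid$phi)
  else {
    pts <- as_points(grid)
    pp <- data.frame(r = sqrt(pts$x^2 + pts$y^2), phi = atan2(pts$y, pts$x))
  }
  if (any(pp$r == 0)) stop("friction-limit maps are singular at r = 0; ",
                           "exclude the core node")
  pp
}

#' Count sign domains of the vorticity on a circle
#'
#' Counts the maximal arcs of constant vorticity sign on a circle around
#' the defect, merging arcs across the periodic seam.  This is the robust,
#' resolution-independent definition of the vortex multiplet order: 4 for
#' the quadruple structure of the +1/2 defect aligned with the gradient, 8
#' for the eightfold -1/2 pattern, 1 when the circulation never changes
#' sign.  Samples with `|omega| < tol` are excluded from sign decisions.
#'
#' @param omega vorticity sampled at equally spaced angles on a circle
#'   (at least 720 samples recommended).
#' @param tol sign tolerance; default `1e-12 * max(abs(omega))`.
#' @return Object of class `vortex_count`: list with `count`, `signs` (the
#'   circular sign sequence), `tol` and `n_samples`.
#' @examples
#' phi <- 2 * pi * (0:1439) / 1440
#' w <- vorticity_map_plus(list(r = rep(1, 1440), phi = phi), theta0 = 0)
#' count_sign_domains(w$value)$count
#' @export
count_sign_domains <- function(omega, tol = NULL) {
  if (inherits(omega, "scalar_field")) omega <- omega$value
  stopifnot(is.numeric(omega), length(omega) >= 8L)
  if (is.null(tol)) tol <- 1e-12 * max(abs(omega))
  s <- sign(omega)[abs(omega) >= tol]
  if (length(s) == 0L)
    stop("all samples below tolerance: vortex count indeterminate")
  runs <- rle(s)$values
  if (length(runs) > 1L && runs[1] == runs[length(runs)])
    runs <- runs[-1L]                       # merge across the periodic seam
  structure(list(count = length(runs), signs = runs, tol = tol,
                 n_samples = length(omega)),
            class = "vortex_count")
}

#' @export
print.vortex_count <- function(x, ...) {
  cat(sprintf("%d sign domain(s) on the circle (%d samples, tol %.3g)\n",
              x$count, x$n_samples, x$tol))
  invisible(x)
}
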