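#' Quasi-static Q-tensor texture of a half-integer defect
#'
#' Evaluates the symmetric traceless order parameter
#' `Qxx = (S0/2) cos(2 q phi + 2 theta0)`, `Qxy = (S0/2) sin(2 q phi + 2 theta0)`
#' (`2 q phi = +phi` for the +1/2 defect, `-phi` for the -1/2 defect,
#' `phi = atan2(y, x)`) on the nodes of a grid.  The phase field is the
#' singular part of the director orientation produced by the defect in the
#' quasi-static approximation; the amplitude is uniform, so
#' `Qxx^2 + Qxy^2 = (S0/2)^2` at every node off the core.
#'
#' @param defect a [defect_config()].
#' @param grid a [make_grid()] grid, or a data frame / list with `x` and `y`.
#' @param r_core optional core-exclusion radius: nodes with `r < r_core` are
#'   returned as `NA`.  A node at the exact core position is a degenerate
#'   input and raises an error unless `r_core` is given.
#' @return A list of class `tensor_field` with elements `grid`, `Qxx`,
#'   `Qxy` (vectors in grid node order) and `units`.
#' @export
q_tensor <- function(defect, grid, r_core = NULL) {
  pts <- as_points(grid)
  r <- sqrt(pts$x^2 + pts$y^2)
  if (is.null(r_core) && any(r == 0))
    stop("grid node at the defect core; supply a core-exclusion radius r_core")
  ph <- atan2(pts$y, pts$x)
  a <- sign(defect$charge) * ph + 2 * defect$theta0
  s <- defect$S0 / 2
  Qxx <- s * cos(a); Qxy <- s * sin(a)
  if (!is.null(r_core)) {
    Qxx[r < r_core] <- NA_real_
    Qxy[r < r_core] <- NA_real_
  }
  structure(list(grid = grid, Qxx = Qxx, Qxy = Qxy, units = "dimensionless"),
            class = "tensor_field")
}

# coerce grid-like input to a data.frame of x, y
as_points <- function(grid) {
  if (inherits(grid, "grid2d")) return(grid_points(grid))
  if (is.data.frame(grid) || is.list(grid)) {
    stopifnot(!is.null(grid$x), !is.null(grid$y))
    return(data.frame(x = grid$x, y = grid$y))
  }
  stop("grid must be a grid2d or a list/data.frame with x and y")
}

# analytic divergence of the defect Q texture (amplitude S0), defect at origin
#  +1/2: div Q = (S0/2) e+ / r
#  -1/2: div Q = (S0/2) (-cos(2 phi - 2 theta0), sin(2 phi - 2 theta0)) / r
div_q <- function(defect, x, y) {
  r <- sqrt(x^2 + y^2)
  s <- defect$S0 / 2
  if (defect$charge > 0) {
    e <- polarization(defect)
    list(x = s * e[1] / r, y = s * e[2] / r)
  } else {
    w <- 2 * atan2(y, x) - 2 * defect$theta0
    list(x = -s * cos(w) / r, y = s * sin(w) / r)
  }
}

#' Active force field induced by a defect in a varying activity
#'
#' The active force is `F = Q . grad(alpha) + alpha div(Q)`, split into an
#' interfacial part `F_I` (from activity gradients) and a bulk part `F_B`
#' (from the defect distortion).  `mode = "closed_form"` dispatches to the
#' analytic expressions for the six supported cases (charge +-1/2 crossed
#' with uniform, linear and step profiles); for the step profile the
#' singular interfacial force concentrated on the line `x = x_v` is returned
#' as a [line_measure()] (an analytic line density), never sampled on the
#' grid.  `mode = "numeric"` computes both terms by centred finite
#' differences on a rectangle grid.
#'
#' @param defect a [defect_config()].
#' @param profile an [activity_profile()].
#' @param grid evaluation grid (`numeric` mode requires a rectangle
#'   [make_grid()] grid).
#' @param mode `"closed_form"` or `"numeric"`.
#' @param r_core optional core-exclusion radius (nodes inside return `NA`).
#' @return List with elements `F_I` and `F_B`.  Each is a `vector_field`
#'   (list with `grid`, `Fx`, `Fy`) except the interfacial part of a step
#'   profile in closed form, which is a `line_measure`.
#' @export
active_force <- function(defect, profile, grid,
                         mode = c("closed_form", "numeric"), r_core = NULL) {
  mode <- match.arg(mode)
  if (mode == "closed_form") active_force_closed(defect, profile, grid, r_core)
  else active_force_numeric(defect, profile, grid, r_core)
}

vector_field <- function(grid, Fx, Fy, units = "rescaled stress / length") {
  structure(list(grid = grid, Fx = Fx, Fy = Fy, units = units),
            class = "vector_field")
}

#' Line-concentrated force measure
#'
#' Represents a force density concentrated on the vertical line `x = x_at`
#' (the delta-function interfacial force of a step activity profile).  The
#' `density` function maps y to a two-column matrix of force per unit line
#' length.  Kinematic evaluators reduce integrals against it to 1D
#' quadratures analytically.
#'
#' @param x_at line position.
#' @param density function(y) -> matrix with columns `Fx`, `Fy`.
#' @return An object of class `line_measure`.
#' @export
line_measure <- function(x_at, density) {
  structure(list(x_at = x_at, density = density), class = "line_measure")
}

active_force_closed <- function(defect, profile, grid, r_core) {
  pts <- as_points(grid)
  x <- pts$x; y <- pts$y
  r <- sqrt(x^2 + y^2)
  if (is.null(r_core) && any(r == 0))
    stop("grid node at the defect core; supply r_core")
  dq <- div_q(defect, x, y)
  alpha <- activity_at(profile, x)
  FB <- vector_field(grid, alpha * dq$x, alpha * dq$y)
  FI <- switch(profile$kind,
    uniform = vector_field(grid, rep(0, length(x)), rep(0, length(x))),
    linear = {
      # Q . grad(alpha) = alphag (Qxx, Qxy)
      qt <- q_tensor(defect, grid, r_core = r_core)
      vector_field(grid, profile$alphag * qt$Qxx, profile$alphag * qt$Qxy)
    },
    step = {
      dens <- step_line_density(defect, profile)
      line_measure(profile$x_v, dens)
    })
  if (!is.null(r_core)) {
    bad <- r < r_core
    FB$Fx[bad] <- NA_real_; FB$Fy[bad] <- NA_real_
    if (inherits(FI, "vector_field")) {
      FI$Fx[bad] <- NA_real_; FI$Fy[bad] <- NA_real_
    }
  }
  list(F_I = FI, F_B = FB)
}

# delta-line density of the step-profile interfacial force:
#   F_I = -dalpha * delta(x - x_v) * (Qxx, Qxy) evaluated on the line
step_line_density <- function(defect, profile) {
  force(defect); force(profile)
  function(y) {
    qt <- q_tensor(defect, list(x = rep(profile$x_v, length(y)), y = y))
    cbind(Fx = -profile$dalpha * qt$Qxx, Fy = -profile$dalpha * qt$Qxy)
  }
}

active_force_numeric <- function(defect, profile, grid, r_core) {
  if (!inherits(grid, "grid2d") || grid$domain != "rectangle")
    stop("numeric mode requires a rectangle grid2d")
  n <- grid$resolution; h <- grid$spacing
  pts <- grid_points(grid)
  r <- matrix(sqrt(pts$x^2 + pts$y^2), n, n)
  if (is.null(r_core) && any(r == 0))
    stop("grid node at the defect core; supply r_core")
  qt <- q_tensor(defect, grid, r_core = r_core)
  Qxx <- matrix(qt$Qxx, n, n); Qxy <- matrix(qt$Qxy, n, n)
  alpha <- matrix(activity_at(profile, pts$x), n, n)
  dx <- function(m) { d <- matrix(NA_real_, n, n)
    d[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * h); d }
  dy <- function(m) { d <- matrix(NA_real_, n, n)
    d[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / (2 * h); d }
  ax <- dx(alpha); ay <- dy(alpha)
  FIx <- Qxx * ax + Qxy * ay
  FIy <- Qxy * ax - Qxx * ay
  FBx <- alpha * (dx(Qxx) + dy(Qxy))
  FBy <- alpha * (dx(Qxy) - dy(Qxx))
  if (!is.null(r_core)) {
    bad <- r < r_core
    FIx[bad] <- FIy[bad] <- FBx[bad] <- FBy[bad] <- NA_real_
  }
  list(F_I = vector_field(grid, as.vector(FIx), as.vector(FIy)),
       F_B = vector_field(grid, as.vector(FBx), as.vector(FBy)))
}
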