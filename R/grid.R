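#' Defect-centred evaluation grids
#'
#' Builds a structured grid centred on the defect core (the origin), either
#' a square of half-width `L` with `resolution x resolution` nodes, or a
#' polar disc of radius `R` with `resolution` radial shells and
#' `2 * resolution` angular nodes (the node `r = 0` is excluded; the defect
#' texture is singular there).  The x axis is the activity-gradient
#' direction.  Node ordering is row-major with x (or r) varying fastest; see
#' [grid_points()].
#'
#' @param domain `"rectangle"` or `"disc"`.
#' @param L half-width of the square domain (rectangle only).
#' @param R disc radius (disc only).
#' @param resolution number of nodes per direction (>= 8).
#' @return An object of class `grid2d`.
#' @examples
#' g <- make_grid("rectangle", L = 2, resolution = 33)
#' nrow(grid_points(g))
#' @export
make_grid <- function(domain = c("rectangle", "disc"), L = 2, R = 5,
                      resolution = 64) {
  domain <- match.arg(domain)
  if (resolution < 8) stop("resolution must be >= 8")
  if (domain == "rectangle") {
    if (L <= 0) stop("half-width L must be > 0")
    x <- seq(-L, L, length.out = resolution)
    structure(list(domain = domain, x = x, y = x, L = L,
                   spacing = x[2] - x[1], resolution = resolution),
              class = "grid2d")
  } else {
    if (R <= 0) stop("radius R must be > 0")
    r <- seq_len(resolution) * (R / resolution)
    phi <- 2 * pi * (seq_len(2 * resolution) - 1) / (2 * resolution)
    structure(list(domain = domain, r = r, phi = phi, R = R,
                   spacing = R / resolution, resolution = resolution),
              class = "grid2d")
  }
}

#' Grid node coordinates
#'
#' Returns the node coordinates of a [make_grid()] grid as a data frame
#' with columns `x`, `y` (and `r`, `phi` for polar coordinates), in the
#' canonical node order: x (rectangle) or r (disc) varying fastest.
#'
#' @param grid a `grid2d`.
#' @return data frame with one row per node.
#' @export
grid_points <- function(grid) {
  if (!inherits(grid, "grid2d")) stop("not a grid2d")
  if (grid$domain == "rectangle") {
    pts <- expand.grid(x = grid$x, y = grid$y, KEEP.OUT.ATTRS = FALSE)
    pts$r <- sqrt(pts$x^2 + pts$y^2)
    pts$phi <- atan2(pts$y, pts$x)
  } else {
    pts <- expand.grid(r = grid$r, phi = grid$phi, KEEP.OUT.ATTRS = FALSE)
    pts$x <- pts$r * cos(pts$phi)
    pts$y <- pts$r * sin(pts$phi)
    pts <- pts[, c("x", "y", "r", "phi")]
  }
  pts
}

#' @export
print.grid2d <- function(x, ...) {
  if (x$domain == "rectangle")
    cat(sprintf("Rectangle grid: [-%g, %g]^2, %d x %d nodes, spacing %g\n",
                x$L, x$L, x$resolution, x$resolution, x$spacing))
  else
    cat(sprintf("Disc grid: R = %g, %d radial x %d angular nodes, dr = %g\n",
                x$R, x$resolution, 2L * x$resolution, x$spacing))
  invisible(x)
}
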