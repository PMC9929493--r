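#' Medium parameters of an active nematic film
#'
#' Bundles the dissipative and elastic constants of the minimal hydrodynamic
#' model of a 2D active nematic on a substrate: substrate friction `Gamma`
#' (stress time / length^2), shear viscosity `eta` (stress time), Frank
#' elastic constant `K` (energy), local ordering strength `g`
#' (energy / length^2) and rotational friction `gamma_rot` (stress time).
#'
#' Derived scales are never stored; they are recomputed on demand by the
#' accessors [dissipation_length()], [coherence_length()],
#' [relaxation_time()] and [zeta()].  The single dimensionless group
#' controlling the flow response is `zeta = ell_d / xi`, the ratio of the
#' hydrodynamic dissipation length `ell_d = sqrt(eta / Gamma)` (crossover
#' between viscosity- and friction-dominated screening) to the nematic
#' coherence length `xi = sqrt(K / g)` (defect core scale).
#'
#' @param Gamma substrate friction coefficient, > 0.
#' @param eta shear viscosity, > 0.
#' @param K nematic elastic constant, > 0.
#' @param g strength of the local ordering potential, > 0.
#' @param gamma_rot rotational friction of the director, > 0.
#' @return An object of class `medium_params`.
#' @examples
#' m <- medium_params()
#' zeta(m)
#' @export
medium_params <- function(Gamma = 1, eta = 1, K = 1, g = 1, gamma_rot = 1) {
  vals <- c(Gamma = Gamma, eta = eta, K = K, g = g, gamma_rot = gamma_rot)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all medium constants must be finite and > 0")
  structure(as.list(vals), class = "medium_params")
}

#' @rdname medium_params
#' @param medium a `medium_params` object.
#' @export
dissipation_length <- function(medium) sqrt(medium$eta / medium$Gamma)

#' @rdname medium_params
#' @export
coherence_length <- function(medium) sqrt(medium$K / medium$g)

#' @rdname medium_params
#' @export
relaxation_time <- function(medium) medium$gamma_rot / medium$g

#' @rdname medium_params
#' @export
zeta <- function(medium) dissipation_length(medium) / coherence_length(medium)

#' @export
print.medium_params <- function(x, ...) {
  cat("Active nematic medium:\n")
  cat(sprintf("  Gamma = %g, eta = %g, K = %g, g = %g, gamma_rot = %g\n",
              x$Gamma, x$eta, x$K, x$g, x$gamma_rot))
  cat(sprintf("  ell_d = %g, xi = %g, tau = %g, zeta = %g\n",
              dissipation_length(x), coherence_length(x),
              relaxation_time(x), zeta(x)))
  invisible(x)
}
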