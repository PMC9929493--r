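# shared fixtures: default medium (Gamma = eta = K = g = 1, so ell_d = xi =
# zeta = 1) and memoized profile-curve tables (the dynamics tests reuse
# them; tabulating the quadratures once keeps the suite fast)

.fixture_env <- new.env(parent = emptyenv())

unit_medium <- function() medium_params(1, 1, 1, 1, 1)

test_curves <- function(charge, need_v = FALSE) {
  key <- paste0("curves_", if (charge > 0) "p" else "m",
                if (need_v) "_v" else "")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <-
      nematicdefects:::default_curves(charge, need_v = need_v)
  .fixture_env[[key]]
}

# gradient of a random polynomial potential; curl-free by construction
poly_grad_force <- function(coef) {
  function(x, y) list(
    Fx = coef[1] + 2 * coef[3] * x + coef[4] * y + 3 * coef[6] * x^2,
    Fy = coef[2] + coef[4] * x + 2 * coef[5] * y + 3 * coef[7] * y^2)
}

expect_close <- function(object, expected, tol = 1e-8) {
  expect_lt(max(abs(object - expected)), tol)
}
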