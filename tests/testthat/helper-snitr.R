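# shared generators for property-style tests

# a random valid parameter set (sum constraints enforced by rescaling)
random_params <- function() {
  scale_triple <- function(x, cap = 0.95) {
    if (sum(x) > cap) x * cap / sum(x) else x
  }
  a <- scale_triple(stats::runif(3, 0.02, 0.6))
  b <- scale_triple(stats::runif(3, 0.02, 0.6))
  ge <- scale_triple(stats::runif(2, 0.02, 0.6))
  snitr_params(mu = stats::runif(1, 0.02, 0.6),
               alpha1 = a[1], alpha2 = a[2], alpha3 = a[3],
               beta1 = b[1], beta2 = b[2], beta3 = b[3],
               gamma1 = ge[1], epsilon = ge[2],
               gamma2 = stats::runif(1, 0.02, 0.6))
}

# a random point on the interior of the 5-simplex
random_simplex_state <- function() {
  x <- stats::rexp(5)
  x / sum(x)
}

expect_params_equal <- function(p, q, tol = 1e-12) {
  expect_equal(unclass(p)[names(unclass(q))], unclass(q),
               tolerance = tol, ignore_attr = TRUE)
}

# monic polynomial coefficients (descending powers, leading 1 dropped)
# from its roots
coef_from_roots <- function(roots) {
  co <- c(1 + 0i)
  for (r in roots) co <- c(co, 0) - c(0, r * co)
  co[-1]
}
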