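test_that("reproduction numbers match the closed forms on known sets", {
  r <- reproduction_numbers(snitr_example_params("infected_persistent"))
  expect_equal(r$r01, 0.2 / (0.4 + 0.15 + 0.18), tolerance = 1e-12)
  expect_equal(round(r$r01, 2), 0.27)
  expect_equal(r$r03, 0.25 / (0.15 + 0.18), tolerance = 1e-12)

  r2 <- reproduction_numbers(snitr_example_params("neglected_persistent"))
  expect_equal(round(r2$r01, 1), 2.6)

  expect_equal(r$r0, max(r$r01, r$r02, r$r03))
})

test_that("next-generation matrix is lower triangular with R0 diagonal", {
  set.seed(44)
  for (i in 1:25) {
    p <- random_params()
    ngm <- next_generation_matrices(p)
    K <- ngm$k_matrix
    expect_equal(K[upper.tri(K)], rep(0, 3), tolerance = 1e-14)
    r <- reproduction_numbers(p)
    expect_equal(unname(diag(K)), c(r$r01, r$r02, r$r03), tolerance = 1e-12)
    # eigenvalues of K equal its diagonal (triangularity)
    ev <- sort(Re(eigen(K, only.values = TRUE)$values))
    expect_equal(ev, sort(unname(diag(K))), tolerance = 1e-10)
    # V times its inverse is the identity
    expect_equal(ngm$v_matrix %*% solve(ngm$v_matrix), diag(3),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("analytic Jacobian matches finite differences", {
  set.seed(55)
  for (i in 1:20) {
    p <- random_params()
    x <- runif(4, 0, 1)
    J_fd <- pracma::jacobian(function(z) snitr_rhs_reduced(z, p), x)
    expect_equal(unname(snitr_jacobian(p, x)), J_fd, tolerance = 1e-6)
  }
})

test_that("rumor-free Jacobian eigenvalues follow the closed-form spectrum", {
  set.seed(66)
  for (i in 1:100) {
    p <- random_params()
    v <- unclass(p)
    expected <- sort(c(
      -v[["mu"]],
      v[["alpha3"]] - v[["beta3"]] - v[["mu"]],
      v[["alpha1"]] - v[["epsilon"]] - v[["gamma1"]] - v[["mu"]],
      v[["alpha2"]] - v[["gamma2"]] - v[["mu"]]
    ))
    ev <- sort(Re(eigen(snitr_jacobian(p, c(1, 0, 0, 0)))$values))
    expect_equal(ev, unname(expected), tolerance = 1e-10)
  }

  # the all-below-one regime has the specific spectrum
  # {-0.63, -0.30, -0.28, -0.23} (from the eigenvalue formulas)
  ev <- sort(Re(eigen(snitr_jacobian(snitr_example_params("rumor_free"),
                                     c(1, 0, 0, 0)))$values))
  expect_equal(ev, c(-0.63, -0.30, -0.28, -0.23), tolerance = 1e-12)
})

test_that("rumor-free stability is equivalent to all R0 components below 1", {
  set.seed(77)
  for (i in 1:100) {
    p <- random_params()
    r <- reproduction_numbers(p)
    ev <- Re(eigen(snitr_jacobian(p, c(1, 0, 0, 0)))$values)
    expect_identical(all(ev < 0), all(c(r$r01, r$r02, r$r03) < 1))
  }
})

test_that("Hurwitz determinants match hand expansion and eigenvalue signs", {
  # (lambda + 1)^4: coefficients 4, 6, 4, 1
  d <- hurwitz_determinants(4, 6, 4, 1)
  expect_equal(unname(d), c(4, 20, 64, 64))

  # delta4 sign identity
  expect_equal(sign(d[["delta4"]]), sign(1) * sign(d[["delta3"]]))

  # agreement with eigenvalue signs over random quartics built from roots
  set.seed(88)
  n_checked <- 0
  for (i in 1:1000) {
    re <- runif(2, -2, 2)
    im <- runif(1, 0, 2)
    roots <- c(re[1], re[2] + c(1i, -1i) * im, runif(1, -2, 2))
    cf <- Re(coef_from_roots(roots))
    d <- hurwitz_determinants(cf[1], cf[2], cf[3], cf[4])
    max_re <- max(Re(roots))
    if (abs(max_re) < 1e-6) next  # skip the marginal band
    n_checked <- n_checked + 1
    if (max_re < 0) {
      expect_true(all(d > 0))
    } else {
      expect_false(all(d > 0))
    }
  }
  expect_gt(n_checked, 900)
})

test_that("classification agrees with the reproduction-number thresholds", {
  st <- classify_stability(snitr_example_params("rumor_free"), "E0")
  expect_identical(st$classification, "stable")
  expect_true(all(st$hurwitz > 0))

  st2 <- classify_stability(snitr_example_params("neglected_persistent"),
                            "E0")
  expect_identical(st2$classification, "unstable")
  expect_gt(st2$reproduction$r01, 1)

  # non-equilibrium points need the force flag
  p <- snitr_example_params("rumor_free")
  expect_error(classify_stability(p, c(0.5, 0.2, 0.2, 0.1)),
               "not an equilibrium")
  expect_s3_class(classify_stability(p, c(0.5, 0.2, 0.2, 0.1),
                                     force = TRUE), "snitr_stability")
})

test_that("classification predicts long-run behaviour from perturbed starts", {
  set.seed(99)
  n_agree <- 0
  n_total <- 0
  for (i in 1:15) {
    p <- random_params()
    st <- classify_stability(p, "E0")
    if (st$classification == "marginal") next
    init <- c(0.97, 0.01, 0.01, 0.01, 0)
    traj <- snitr_integrate(p, init = init, t_end = 300, n_points = 150)
    endpoint <- as.numeric(traj[nrow(traj), c("S", "N", "I", "T")])
    returned <- max(abs(endpoint - c(1, 0, 0, 0))) < 1e-3
    n_total <- n_total + 1
    if (returned == (st$classification == "stable")) n_agree <- n_agree + 1
  }
  expect_identical(n_agree, n_total)
})

test_that("reproduction numbers are monotone in their parameters", {
  p <- snitr_example_params("rumor_free")
  v <- unclass(p)
  bump <- function(nm, dx) {
    w <- v
    w[[nm]] <- w[[nm]] + dx
    reproduction_numbers(structure(w, class = "snitr_params"))
  }
  base <- reproduction_numbers(p)
  expect_gt(bump("alpha1", 0.05)$r01, base$r01)
  expect_lt(bump("epsilon", 0.05)$r01, base$r01)
  expect_lt(bump("gamma1", 0.05)$r01, base$r01)
  expect_lt(bump("mu", 0.05)$r01, base$r01)
  expect_gt(bump("alpha2", 0.05)$r02, base$r02)
  expect_lt(bump("gamma2", 0.05)$r02, base$r02)
  expect_gt(bump("alpha3", 0.05)$r03, base$r03)
  expect_lt(bump("beta3", 0.05)$r03, base$r03)
})

test_that("multi-start convergence check detects the global regime", {
  p <- snitr_example_params("rumor_free")  # all three R0 components < 1
  chk <- global_convergence_check(p, n_starts = 20, seed = 5, t_end = 200)
  expect_equal(chk$fraction, 1)
  expect_true(all(chk$runs$eventually_decreasing))

  # an R01 > 1 regime does not return to the rumor-free state
  p2 <- snitr_example_params("coexistence")
  chk2 <- global_convergence_check(p2, n_starts = 10, seed = 5, t_end = 200)
  expect_lt(chk2$fraction, 1)

  # reproducibility under the seed
  chk3 <- global_convergence_check(p, n_starts = 5, seed = 9)
  chk4 <- global_convergence_check(p, n_starts = 5, seed = 9)
  expect_equal(chk3$runs, chk4$runs)
})
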