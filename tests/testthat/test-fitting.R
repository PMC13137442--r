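test_that("fit coefficient reproduces hand-computed R^2 values", {
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 3)), 1)
  # constant prediction at the observed mean scores exactly 0
  obs <- c(0.1, 0.2, 0.3)
  expect_equal(goodness_of_fit(rep(mean(obs), 3), obs), 0)
  # 1 - 0.01/0.02 = 0.5
  expect_equal(goodness_of_fit(c(0.1, 0.2, 0.4), obs), 0.5)

  expect_error(goodness_of_fit(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(goodness_of_fit(c(1, 2), c(1, 1)), "variance")
})

test_that("small-scale noiseless round trip recovers the curve", {
  s <- generate_series(duration = 13, bin_width = 0.25, noise = "none")
  fv <- fit_and_validate(s, n_starts = 12, n_polish = 3, n_hops = 10,
                         max_rounds_total = 40, seed = 7,
                         init = snitr_default_init())
  obs <- tibble::as_tibble(s)
  in_fit <- obs$time <= attr(s, "fit_window_end")
  rmse_fit <- sqrt(mean((fv$fit$predicted$value[in_fit] -
                           obs$value[in_fit])^2))
  expect_lt(rmse_fit, 1e-4)
  # out-of-window prediction quality on this shortened series is weaker
  # than at full scale (fewer points, less curvature); the full-length
  # round trip asserts validation R^2 > 0.99
  expect_gt(fv$validation_fit_coefficient, 0.8)
})

test_that("estimates respect the box bounds and improve on every start", {
  s <- generate_series(duration = 13, bin_width = 0.25, noise = "poisson",
                       seed = 12)
  f <- fit_snitr(s, n_starts = 6, n_polish = 2, n_hops = 2,
                 max_rounds_total = 6, maxiter = 60, seed = 3)
  est <- unclass(f$params_hat)
  expect_true(all(est >= 0.001 & est <= 0.999))
  expect_true(all(f$rss <= f$start_rss))
  expect_gte(f$rss, 0)
  expect_lte(f$fit_coefficient, 1)
})

test_that("fits are deterministic given the seed", {
  s <- generate_series(duration = 13, bin_width = 0.25, noise = "poisson",
                       seed = 9)
  f1 <- fit_snitr(s, n_starts = 4, n_polish = 1, n_hops = 1,
                  max_rounds_total = 3, maxiter = 40, seed = 11)
  f2 <- fit_snitr(s, n_starts = 4, n_polish = 1, n_hops = 1,
                  max_rounds_total = 3, maxiter = 40, seed = 11)
  expect_identical(unclass(f1$params_hat), unclass(f2$params_hat))
  expect_identical(f1$rss, f2$rss)
})

test_that("observation order does not change the fit", {
  s <- generate_series(duration = 13, bin_width = 0.25, noise = "poisson",
                       seed = 9)
  shuffled <- tibble::as_tibble(s)[sample(nrow(s)), ]
  attr(shuffled, "fit_window_end") <- attr(s, "fit_window_end")
  attr(shuffled, "validation_end") <- attr(s, "validation_end")
  f1 <- fit_snitr(s, n_starts = 3, n_polish = 1, n_hops = 0,
                  max_rounds_total = 2, maxiter = 40, seed = 2)
  f2 <- fit_snitr(shuffled, n_starts = 3, n_polish = 1, n_hops = 0,
                  max_rounds_total = 2, maxiter = 40, seed = 2)
  expect_equal(unclass(f1$params_hat), unclass(f2$params_hat),
               tolerance = 1e-12)
})

test_that("series starting at the exact model curve scores near-zero rss", {
  s <- generate_series(duration = 13, bin_width = 0.25, noise = "none")
  # evaluate the objective at the generating configuration itself
  f <- fit_snitr(s, n_starts = 1, n_polish = 1, n_hops = 0, seed = 1,
                 init = snitr_default_init(),
                 fixed_params = unclass(attr(s, "params")))
  expect_lt(f$rss, 1e-12)
})

test_that("empty validation window is an error", {
  s <- generate_series(duration = 13, bin_width = 0.5, noise = "none")
  trimmed <- dplyr::filter(tibble::as_tibble(s), .data$time <= 6)
  attr(trimmed, "fit_window_end") <- 6
  attr(trimmed, "validation_end") <- 13
  expect_error(fit_and_validate(trimmed), "validation window")
})

test_that("too few fit-window observations are rejected", {
  s <- generate_series(duration = 13, bin_width = 1, noise = "none")
  expect_error(fit_snitr(s), "at least 20")
})
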