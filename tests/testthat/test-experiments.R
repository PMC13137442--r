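test_that("density experiments reach the documented steady states", {
  # all-R0-below-1 regime returns to the rumor-free state
  out <- run_density_experiment(snitr_example_params("rumor_free"),
                                t_end = 200)
  expect_equal(as.numeric(out$summary[, c("S", "N", "I", "T")]),
               c(1, 0, 0, 0), tolerance = 1e-3)

  # transmitter-free regime: T vanishes at the steady state
  out2 <- run_density_experiment(snitr_example_params("neglected_persistent"),
                                 t_end = 400)
  expect_lt(out2$summary$T, 1e-3)

  # starting at the rumor-free state stays there
  out3 <- run_density_experiment(snitr_example_params("rumor_free"),
                                 init = c(1, 0, 0, 0, 0), t_end = 50)
  expect_equal(as.numeric(out3$summary[, c("S", "N", "I", "T", "R")]),
               c(1, 0, 0, 0, 0))
})

test_that("documented sweep monotonicities hold for the bundled configs", {
  cfgs <- snitr_sweep_configs()
  peaks <- lapply(cfgs, function(cfg) {
    sw <- sweep_parameter(snitr_example_params(cfg$base), cfg$name,
                          cfg$values, compartment = cfg$compartment,
                          t_end = 100, n_points = 300)
    sw$summaries$peak
  })
  # infected peak rises with alpha1 and beta1, falls with epsilon
  expect_true(all(diff(peaks$I_alpha1) > 0))
  expect_true(all(diff(peaks$I_beta1) > 0))
  expect_true(all(diff(peaks$I_epsilon) < 0))
  # transmitter peak rises with alpha2, beta2 and epsilon
  expect_true(all(diff(peaks$T_alpha2) > 0))
  expect_true(all(diff(peaks$T_beta2) > 0))
  expect_true(all(diff(peaks$T_epsilon) > 0))
})

test_that("sweeps flag invalid parameter combinations instead of dropping", {
  p <- snitr_example_params("rumor_free")  # alpha2 + alpha3 = 0.63
  sw <- sweep_parameter(p, "alpha1", c(0.2, 0.5), compartment = "I",
                        t_end = 20, n_points = 50)
  expect_equal(nrow(sw$summaries), 2)
  expect_true(sw$summaries$valid[1])   # 0.2 + 0.63 <= 1
  expect_false(sw$summaries$valid[2])  # 0.5 + 0.63 > 1
})

test_that("a single-value sweep reduces to the density experiment", {
  p <- snitr_example_params("infected_transmitter")
  sw <- sweep_parameter(p, "alpha1", unclass(p)[["alpha1"]],
                        compartment = "I", t_end = 50, n_points = 100)
  ref <- run_density_experiment(p, t_end = 50, n_points = 100)
  expect_equal(sw$summaries$final, ref$summary$I, tolerance = 1e-10)
  expect_equal(nrow(sw$summaries), 1)
})

test_that("sensitivity grids are monotone as the closed forms dictate", {
  p <- snitr_example_params("rumor_free")
  g1 <- sensitivity_grid(p, "r01", list(alpha1 = seq(0.05, 0.6, by = 0.05)))
  expect_true(all(diff(g1$r01) > 0))
  g2 <- sensitivity_grid(p, "r02", list(gamma2 = seq(0.05, 0.6, by = 0.05)))
  expect_true(all(diff(g2$r02) < 0))
  g3 <- sensitivity_grid(p, "r03", list(beta3 = seq(0.05, 0.6, by = 0.05)))
  expect_true(all(diff(g3$r03) < 0))

  # two-axis grid has product shape
  g4 <- sensitivity_grid(p, "r01", list(alpha1 = c(0.1, 0.2, 0.3),
                                        epsilon = c(0.1, 0.2)))
  expect_equal(nrow(g4), 6)

  # single point equals the scalar value
  g5 <- sensitivity_grid(p, "r01", list(alpha1 = 0.25))
  expect_equal(g5$r01, reproduction_numbers(p)$r01)
})

test_that("immediate transmitter entry reproduces the unmodified run", {
  p <- snitr_example_params("infected_transmitter")
  iv <- delayed_transmitter_run(p, t_enter = 0, t_end = 60, n_points = 200)
  ref <- snitr_integrate(p, t_end = 60, n_points = 200)
  expect_equal(iv$max_i, max(ref$I), tolerance = 1e-10)
  expect_equal(iv$max_t, max(ref$T), tolerance = 1e-10)
})

test_that("later transmitter entry weakens rumor suppression", {
  p <- snitr_example_params("intervention_demo")
  grid <- c(1, 5, 10, 17, 25)
  runs <- lapply(grid, function(tt) {
    delayed_transmitter_run(p, t_enter = tt, seed_fraction = 0.05,
                            t_end = 80, n_points = 600)
  })
  max_i <- vapply(runs, `[[`, numeric(1), "max_i")
  max_t <- vapply(runs, `[[`, numeric(1), "max_t")
  expect_true(all(diff(max_i) >= -1e-6))
  expect_true(all(diff(max_t) <= 1e-6))
  # entering first is strictly better than entering last
  expect_lt(max_i[1], max_i[length(max_i)])
  expect_gt(max_t[1], max_t[length(max_t)])
})

test_that("intervention conserves density across the activation jump", {
  p <- snitr_example_params("infected_transmitter")
  iv <- delayed_transmitter_run(p, t_enter = 10, seed_fraction = 0.05,
                                t_end = 40, n_points = 400)
  tr <- iv$trajectory
  total <- tr$S + tr$N + tr$I + tr$T + tr$R
  expect_lt(max(abs(total - 1)), 1e-9)
  expect_error(delayed_transmitter_run(p, t_enter = 50, t_end = 40),
               "t_enter")
})
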