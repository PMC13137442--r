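#' Coefficient of determination between predicted and observed series
#'
#' The "fit coefficient" used throughout the package is the coefficient of
#' determination \eqn{R^2 = 1 - SS_{res} / SS_{tot}} between an observed
#' series and the model-predicted one, computed on matched points.
#'
#' @param predicted,observed Numeric vectors of equal length (>= 2).
#' @return A single number, at most 1 (negative when the model fits worse
#'   than the observed mean).
#' @examples
#' goodness_of_fit(c(0.1, 0.2, 0.4), c(0.1, 0.2, 0.3))
#' @export
goodness_of_fit <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  if (length(observed) < 2) stop("need at least 2 points", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("observed series has zero variance; R^2 undefined", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Fit SNITR parameters to a binned I+T series
#'
#' Bounded least squares on the fitting window of an observed
#' infected-plus-transmitter density series: minimises
#' \eqn{\sum_t (I(t) + T(t) - y_t)^2} over the ten rates, each box-bounded
#' to `[0.001, 0.999]`. The rates are optimised on the log scale (they are
#' positive scale parameters spanning decades), from seeded Latin-hypercube
#' multi-starts, with restarted Levenberg-Marquardt polishing of the
#' best-scoring starts and optional basin-hopping perturbations of the
#' incumbent. The initial compartment state is co-estimated by default
#' (`S0, N0, I0, T0` free on the simplex, `R0` the remainder); pass `init`
#' to pin it — recommended whenever the observation protocol fixes the
#' starting state, as in synthetic round-trip studies. With only the I+T
#' aggregate observed the ten-rate model is not fully identifiable, so the
#' contract of this fit is curve recovery, not parameter recovery.
#'
#' @param observed A [generate_series()] / [read_series()] object (class
#'   `snitr_series`). At least 20 observation points must fall inside the
#'   fitting window.
#' @param n_starts Number of Latin-hypercube starting points.
#' @param n_polish How many of the best-scoring starts receive full
#'   Levenberg-Marquardt polishing.
#' @param n_rounds Maximum Levenberg-Marquardt restarts per polished
#'   start; each restart resets the trust region, which keeps descending
#'   along the sloppy valleys of the objective. Restarting stops early
#'   once a round improves the objective by less than 3%.
#' @param n_hops Basin-hopping steps: seeded log-normal jitters of the
#'   incumbent, each followed by a short polish; improvements are kept.
#' @param seed RNG seed (Latin hypercube and hops); the fit is
#'   deterministic given the seed.
#' @param init Optional fixed initial state (5 densities); if `NULL` the
#'   initial state is estimated.
#' @param fixed_params Optional named numeric vector of rates to hold
#'   fixed (e.g. `c(mu = 0.001)`).
#' @param lower,upper Box bounds on every estimated rate.
#' @param rtol,atol Solver tolerances used inside the objective.
#' @param maxiter Levenberg-Marquardt iteration cap per round.
#' @param max_rounds_total Deterministic budget: total Levenberg-Marquardt
#'   rounds across all polished starts and hops.
#' @param rss_tol Convergence target: optimisation stops once the
#'   objective falls below this value (machine-precision fit for
#'   density-scale data).
#' @return An object of class `snitr_fit`: list with `params_hat`
#'   (`snitr_params`), `init_hat`, `rss`, `fit_coefficient` (R^2 on the
#'   fitting window), `n_starts`, `seed`, `converged`, `predicted` (tibble
#'   `time, value` over all observation times) and `start_rss` (initial
#'   objective at every start). Supports `tidy()`, `glance()` and
#'   `autoplot()`.
#' @examples
#' \donttest{
#' s <- generate_series(duration = 20, bin_width = 0.5)
#' f <- fit_snitr(s, n_starts = 4, n_polish = 1, seed = 1)
#' glance(f)
#' }
#' @export
fit_snitr <- function(observed, n_starts = 16, n_polish = 4, n_rounds = 10,
                      n_hops = 0, seed = 1234,
                      init = NULL, fixed_params = NULL,
                      lower = 0.001, upper = 0.999,
                      rtol = 1e-8, atol = 1e-10, maxiter = 150,
                      max_rounds_total = 30, rss_tol = 1e-12) {
  stopifnot(inherits(observed, "snitr_series") || is.data.frame(observed))
  fit_end <- attr(observed, "fit_window_end")
  obs <- dplyr::arrange(tibble::as_tibble(observed)[c("time", "value")],
                        .data$time)
  in_fit <- obs$time <= fit_end
  if (sum(in_fit) < 20) {
    stop("need at least 20 observation points in the fitting window",
         call. = FALSE)
  }
  t_fit <- obs$time[in_fit]
  y_fit <- obs$value[in_fit]

  rate_names <- c("mu", "alpha1", "alpha2", "alpha3",
                  "beta1", "beta2", "beta3", "gamma1", "gamma2", "epsilon")
  fixed <- fixed_params
  free_rates <- setdiff(rate_names, names(fixed))
  k <- length(free_rates)
  estimate_init <- is.null(init)
  n_theta <- k + if (estimate_init) 4 else 0

  # rates are carried as log-rates; the init block (if any) stays linear
  lo <- c(rep(log(lower), k), rep(0, n_theta - k))
  hi <- c(rep(log(upper), k), rep(1, n_theta - k))

  unpack <- function(theta) {
    p <- stats::setNames(numeric(10), rate_names)
    p[free_rates] <- exp(theta[seq_len(k)])
    p[names(fixed)] <- fixed
    if (estimate_init) {
      st <- pmax(theta[k + 1:4], 0)
      if (sum(st) > 1) st <- st / sum(st)   # project back onto the simplex
      init5 <- c(st, 1 - sum(st))
    } else {
      init5 <- as.numeric(init)
    }
    list(params = structure(p, class = "snitr_params"), init = init5)
  }

  residual_fun <- function(theta) {
    u <- unpack(theta)
    pred <- tryCatch(
      model_it_curve(u$params, u$init, t_fit, rtol = rtol, atol = atol),
      error = function(e) NULL
    )
    if (is.null(pred) || any(!is.finite(pred))) {
      return(rep(sqrt(1e6 / length(t_fit)), length(t_fit)))
    }
    pred - y_fit
  }

  rounds_left <- max_rounds_total
  polish <- function(theta, rounds) {
    out <- list(theta = theta, rss = sum(residual_fun(theta)^2),
                converged = FALSE)
    rss_prev <- Inf
    for (round in seq_len(rounds)) {
      if (rounds_left <= 0 || out$rss < rss_tol) break
      rounds_left <<- rounds_left - 1
      res <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(par = theta, lower = lo, upper = hi,
                             fn = residual_fun,
                             control = minpack.lm::nls.lm.control(
                               maxiter = maxiter, ptol = 1e-12,
                               ftol = 1e-14))),
        error = function(e) NULL
      )
      if (is.null(res)) break
      theta <- res$par
      rss_j <- sum(res$fvec^2)
      if (rss_j < out$rss) {
        out <- list(theta = theta, rss = rss_j,
                    converged = res$info %in% 1:4)
      }
      if (rss_j > 0.97 * rss_prev) break  # stalled
      rss_prev <- rss_j
    }
    out
  }

  if (n_theta == 0) {
    # everything pinned: evaluate, nothing to optimise
    u <- unpack(numeric(0))
    best <- list(theta = numeric(0), rss = sum(residual_fun(numeric(0))^2),
                 converged = TRUE)
    start_rss <- best$rss
  } else {
    # seeded Latin-hypercube multi-start, log-uniform over the rate box
    set.seed(seed)
    u01 <- lhs::randomLHS(n_starts, n_theta)
    starts <- sweep(sweep(u01, 2, hi - lo, "*"), 2, lo, "+")
    if (estimate_init) {
      # bias starts towards mostly-susceptible initial states
      starts[, k + 1] <- 0.7 + 0.29 * u01[, k + 1]            # S0
      starts[, k + 2:4] <- 0.1 * u01[, k + 2:4, drop = FALSE] # N0, I0, T0
    }
    start_rss <- apply(starts, 1, function(th) sum(residual_fun(th)^2))
    order_idx <- order(start_rss)
    polish_idx <- order_idx[seq_len(min(n_polish, n_starts))]

    best <- list(theta = starts[order_idx[1], ], rss = start_rss[order_idx[1]],
                 converged = FALSE)
    for (j in polish_idx) {
      if (best$rss < rss_tol) break
      cand <- polish(starts[j, ], n_rounds)
      if (cand$rss < best$rss) best <- cand
    }
    for (h in seq_len(n_hops)) {
      if (rounds_left <= 0 || best$rss < rss_tol) break
      jit <- stats::rnorm(n_theta, 0, 0.15)
      th <- pmin(pmax(best$theta + jit, lo), hi)
      cand <- polish(th, max(2, n_rounds %/% 3))
      if (cand$rss < best$rss) best <- cand
    }
  }

  u <- unpack(best$theta)
  pred_all <- model_it_curve(u$params, u$init, obs$time,
                             rtol = rtol, atol = atol)
  r2_fit <- goodness_of_fit(pred_all[in_fit], y_fit)
  structure(list(
    params_hat = u$params,
    init_hat = stats::setNames(u$init, c("S", "N", "I", "T", "R")),
    rss = best$rss,
    fit_coefficient = r2_fit,
    n_starts = n_starts, seed = seed,
    converged = best$converged,
    predicted = tibble::tibble(time = obs$time, value = pred_all),
    observed = obs,
    fit_window_end = fit_end,
    start_rss = start_rss
  ), class = "snitr_fit")
}

#' Fit on the fitting window, score on the validation window
#'
#' Runs [fit_snitr()] on the fitting window, integrates the fitted model
#' forward, and computes the fit coefficient (R^2) on the validation
#' window only — the out-of-sample check that the fitted dynamics predict
#' the later course of the series.
#'
#' @inheritParams fit_snitr
#' @param ... Passed to [fit_snitr()].
#' @return A list with `fit` (the `snitr_fit`) and
#'   `validation_fit_coefficient`.
#' @export
fit_and_validate <- function(observed, ...) {
  fit_end <- attr(observed, "fit_window_end")
  val_end <- attr(observed, "validation_end")
  obs <- tibble::as_tibble(observed)
  in_val <- obs$time > fit_end & obs$time <= val_end
  if (sum(in_val) == 0) stop("empty validation window", call. = FALSE)
  fit <- fit_snitr(observed, ...)
  r2_val <- goodness_of_fit(fit$predicted$value[in_val],
                            obs$value[in_val])
  list(fit = fit, validation_fit_coefficient = r2_val)
}

#' @export
print.snitr_fit <- function(x, ...) {
  cat(sprintf(paste0("<snitr_fit>  RSS %.4g, fit-window R^2 %.4f ",
                     "(%d starts, seed %d)%s\n"),
              x$rss, x$fit_coefficient, x$n_starts, x$seed,
              if (x$converged) "" else "  [not converged]"))
  print(x$params_hat)
  invisible(x)
}

#' @method tidy snitr_fit
#' @export
tidy.snitr_fit <- function(x, ...) {
  tibble::tibble(term = names(unclass(x$params_hat)),
                 estimate = as.numeric(unclass(x$params_hat)))
}

#' @method glance snitr_fit
#' @export
glance.snitr_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, fit_coefficient = x$fit_coefficient,
                 n_starts = x$n_starts, seed = x$seed,
                 converged = x$converged,
                 n_obs_fit = sum(x$observed$time <= x$fit_window_end))
}
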