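#' Closed-form equilibrium candidates
#'
#' Evaluate the published closed-form expressions for the seven candidate
#' steady states of the reduced system: the rumor-free point E0 = (1,0,0,0)
#' and the boundary/coexistence candidates E1-E6 (which compartments of
#' N, I, T are occupied). The expressions are evaluated exactly as
#' published; several of them are internally inconsistent with the vector
#' field (see the consistency vignette), so every point carries its
#' residual `max |rhs|` and a feasibility flag rather than being trusted.
#' Candidates whose denominators vanish are returned as undefined (`NA`
#' components) instead of raising.
#'
#' @param params A [snitr_params()] object.
#' @param feas_tol Components within `[-feas_tol, 1 + feas_tol]` count as
#'   feasible (after clipping for the flag only; coordinates are reported
#'   unclipped).
#' @return A tibble with columns `label, S, N, I, T, feasible, residual,
#'   source, defined`; one row per candidate, `source = "closed_form"`.
#' @examples
#' closed_form_equilibria(snitr_example_params("infected_persistent"))
#' @export
closed_form_equilibria <- function(params, feas_tol = 1e-9) {
  p <- as.list(unclass(params))
  safe_div <- function(num, den) if (abs(den) < 1e-14) NA_real_ else num / den

  s1 <- safe_div(p$gamma2 + p$mu, p$alpha2)
  e1 <- c(s1, 0, 0,
          safe_div(p$mu, p$gamma2 + p$mu) - safe_div(p$mu, p$alpha2))

  e2 <- c(s1, 0,
          safe_div(p$mu * (p$alpha2 - p$gamma2 - p$mu),
                   p$alpha2 * (p$gamma2 + p$mu)), 0)

  s3 <- safe_div(p$beta3 + p$mu, p$alpha3)
  e3 <- c(s3,
          safe_div(p$mu * (p$alpha3 - p$beta3 - p$mu),
                   p$alpha3 * (p$beta3 + p$mu)), 0, 0)

  s4 <- safe_div(p$epsilon + p$gamma1 + p$mu, p$alpha1)
  den4 <- if (is.na(s4)) NA_real_ else {
    p$alpha1 * (p$gamma2 + p$mu - p$alpha2 * s4) + p$alpha2 * p$epsilon
  }
  e4 <- if (is.na(s4) || is.na(den4)) rep(NA_real_, 4) else {
    pre <- p$mu * safe_div(1 - s4, s4)
    c(s4, 0,
      safe_div(pre * (p$gamma2 + p$mu - p$alpha2 * s4), den4),
      safe_div(pre * p$epsilon, den4))
  }

  s5 <- safe_div(p$mu * p$beta2,
                 p$alpha3 * p$gamma2 + p$alpha3 * p$mu + p$mu * p$beta2 -
                   p$alpha2 * p$beta3 - p$alpha2 * p$mu)
  e5 <- if (is.na(s5)) rep(NA_real_, 4) else {
    c(s5,
      safe_div(p$gamma2 + p$mu - p$alpha2 * s5, p$beta2), 0,
      safe_div(p$alpha3 * s5 - p$beta3 - p$mu, p$beta2))
  }

  # published coexistence expressions (kept as printed; diagnosed by residual)
  s6 <- safe_div(p$epsilon * (p$beta3 + p$mu + p$beta2) +
                   p$beta1 * (p$gamma2 + p$mu) -
                   p$beta2 * (p$epsilon + p$gamma1 + p$mu),
                 p$beta1 * p$alpha2 - p$beta2 * p$alpha1 +
                   p$epsilon * p$alpha3)
  e6 <- if (is.na(s6)) rep(NA_real_, 4) else {
    n6 <- safe_div(p$epsilon + p$gamma1 + p$mu - p$alpha1 * s6, p$beta1)
    t6 <- if (is.na(n6)) NA_real_ else {
      p$epsilon * p$beta1 *
        (p$gamma2 + p$mu - p$alpha2 * s6 - p$beta2 * n6) +
        p$beta2 * p$epsilon * (p$alpha3 * s6 - p$beta3 - p$mu)
    }
    i6 <- if (is.na(n6) || is.na(t6)) NA_real_ else {
      safe_div((p$gamma2 + p$mu - p$alpha2 * s6 - p$beta2 * n6) * t6,
               p$epsilon)
    }
    c(s6, n6, i6, t6)
  }

  pts <- list(E0 = c(1, 0, 0, 0), E1 = e1, E2 = e2, E3 = e3,
              E4 = e4, E5 = e5, E6 = e6)
  purrr::imap_dfr(pts, function(x, lab) {
    defined <- all(is.finite(x))
    res <- if (defined) max(abs(snitr_rhs_reduced(x, params))) else NA_real_
    tibble::tibble(
      label = lab, S = x[1], N = x[2], I = x[3], T = x[4],
      feasible = defined && all(x >= -feas_tol) && all(x <= 1 + feas_tol),
      residual = res, source = "closed_form", defined = defined
    )
  })
}

#' Numeric equilibrium of the reduced system
#'
#' Finds a root of [snitr_rhs_reduced()] by damped Newton iteration using
#' the analytic Jacobian, starting from `guess`. The returned point is
#' labelled from its occupancy pattern (which of N, I, T are nonzero) and
#' carries its residual; non-convergence is reported, not raised.
#'
#' @param params A [snitr_params()] object.
#' @param guess Numeric vector `(S, N, I, T)` in `[0, 1]^4`.
#' @param tol Required `max |rhs|` at the root.
#' @param max_iter Newton iteration cap.
#' @return A one-row tibble like [closed_form_equilibria()] with
#'   `source = "numeric"` and an extra `converged` column.
#' @export
find_equilibrium_numeric <- function(params, guess, tol = 1e-10,
                                     max_iter = 200) {
  stopifnot(length(guess) == 4)
  if (any(guess < 0) || any(guess > 1)) {
    stop("guess must lie in [0, 1]^4", call. = FALSE)
  }
  x <- as.numeric(guess)
  f <- snitr_rhs_reduced(x, params)
  for (k in seq_len(max_iter)) {
    if (max(abs(f)) < tol) break
    J <- snitr_jacobian(params, x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) {
      step <- -c(MASS_ginv(J) %*% f)
    }
    lambda <- 1
    repeat {
      x_new <- x + lambda * step
      f_new <- tryCatch(snitr_rhs_reduced(x_new, params),
                        error = function(e) rep(Inf, 4))
      if (max(abs(f_new)) < max(abs(f)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- x_new
    f <- f_new
  }
  res <- max(abs(f))
  converged <- is.finite(res) && res < tol
  lab <- if (converged) occupancy_label(x) else "numeric"
  tibble::tibble(
    label = lab, S = x[1], N = x[2], I = x[3], T = x[4],
    feasible = all(x >= -1e-9) && all(x <= 1 + 1e-9),
    residual = res, source = "numeric", defined = TRUE,
    converged = converged
  )
}

# Moore-Penrose fallback without importing MASS for one call
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

occupancy_label <- function(x, tol = 1e-6) {
  occ <- x[2:4] > tol  # N, I, T
  key <- paste(as.integer(occ), collapse = "")
  switch(key,
         "000" = "E0", "001" = "E1", "010" = "E2", "100" = "E3",
         "011" = "E4", "101" = "E5", "111" = "E6", "numeric")
}

#' Closed-form vs numeric consistency report
#'
#' For each defined closed-form candidate, reports whether it is a genuine
#' root of the reduced system (residual below `root_tol`) and the distance
#' to the nearest numerically refined root (Newton started from the
#' candidate itself and from the long-run integration endpoint).
#'
#' @param params A [snitr_params()] object.
#' @param root_tol Residual below which a candidate counts as a true root.
#' @param t_end Horizon of the long-run integration used to seed one root.
#' @return A tibble with one row per defined closed-form candidate:
#'   `label, S, N, I, T, feasible, residual, is_root, nearest_root_dist`.
#' @export
consistency_report <- function(params, root_tol = 1e-8, t_end = 400) {
  cf <- dplyr::filter(closed_form_equilibria(params), .data$defined)

  # candidate numeric roots: refine each closed form + the attractor
  traj <- snitr_integrate(params, t_end = t_end, n_points = 200)
  endpoint <- as.numeric(traj[nrow(traj), c("S", "N", "I", "T")])
  guesses <- c(
    purrr::map(seq_len(nrow(cf)), function(i) {
      pmin(pmax(as.numeric(cf[i, c("S", "N", "I", "T")]), 0), 1)
    }),
    list(endpoint)
  )
  roots <- purrr::map_dfr(guesses, function(g) {
    find_equilibrium_numeric(params, g)
  })
  roots <- dplyr::filter(roots, .data$converged)

  dist_to_nearest <- function(pt) {
    if (nrow(roots) == 0) return(NA_real_)
    min(sqrt((roots$S - pt[1])^2 + (roots$N - pt[2])^2 +
               (roots$I - pt[3])^2 + (roots$T - pt[4])^2))
  }
  cf |>
    dplyr::rowwise() |>
    dplyr::mutate(
      is_root = .data$residual < root_tol,
      nearest_root_dist = dist_to_nearest(c(.data$S, .data$N,
                                            .data$I, .data$T))
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"source", -"defined")
}
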