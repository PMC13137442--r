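#' Density-evolution experiment
#'
#' Integrates the model and summarises the endpoint: final densities, the
#' residual `max |rhs|` there, and whether a steady state was reached.
#'
#' @inheritParams snitr_integrate
#' @param ... Passed to [snitr_integrate()].
#' @return A list with `trajectory` (a `snitr_trajectory`) and `summary`
#'   (one-row tibble `S, N, I, T, R, endpoint_residual, steady_state`).
#' @examples
#' run_density_experiment(snitr_example_params("rumor_free"))$summary
#' @export
run_density_experiment <- function(params, init = snitr_default_init(),
                                   t_end = 200, ...) {
  traj <- snitr_integrate(params, init = init, t_end = t_end, ...)
  d <- attr(traj, "diagnostics")
  last <- traj[nrow(traj), ]
  list(
    trajectory = traj,
    summary = tibble::tibble(
      S = last$S, N = last$N, I = last$I, T = last$T, R = last$R,
      endpoint_residual = d$endpoint_residual,
      steady_state = d$steady_state
    )
  )
}

#' Parameter sweep of a density trajectory
#'
#' Re-runs the model with one rate swept over a value grid, from one shared
#' initial condition and time grid, and summarises a chosen compartment per
#' value: peak density, time of peak, and final density. Values whose
#' resulting parameter set violates the sum constraints are flagged
#' (`valid = FALSE`) but still integrated, never silently dropped.
#'
#' @param base_params A [snitr_params()] object.
#' @param name Name of the swept rate (e.g. `"alpha1"`).
#' @param values Numeric vector of values for the swept rate.
#' @param init Shared initial condition.
#' @param t_end Shared horizon.
#' @param compartment One of `"S", "N", "I", "T", "R"` to summarise.
#' @param n_points Grid resolution per run.
#' @return A list of class `snitr_sweep` with `summaries` (tibble: one row
#'   per swept value with `value, valid, peak, t_peak, final`),
#'   `trajectories` (named list), and the sweep settings.
#' @examples
#' cfg <- snitr_sweep_configs()$I_alpha1
#' sw <- sweep_parameter(snitr_example_params(cfg$base), cfg$name,
#'                       cfg$values, compartment = "I", t_end = 60)
#' sw$summaries
#' @export
sweep_parameter <- function(base_params, name, values,
                            init = snitr_default_init(), t_end = 100,
                            compartment = "I", n_points = 400) {
  stopifnot(name %in% names(unclass(base_params)),
            compartment %in% c("S", "N", "I", "T", "R"),
            length(values) >= 1)
  check_init(init)
  runs <- purrr::map(values, function(v) {
    p <- unclass(base_params)
    p[[name]] <- v
    valid <- tryCatch({
      validate_snitr_params(p, strict = TRUE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) TRUE)
    pars <- structure(p, class = "snitr_params")
    traj <- snitr_integrate(pars, init = init, t_end = t_end,
                            n_points = n_points)
    y <- traj[[compartment]]
    k <- which.max(y)
    list(valid = valid, traj = traj,
         summary = tibble::tibble(value = v, valid = valid,
                                  peak = y[k], t_peak = traj$time[k],
                                  final = y[length(y)]))
  })
  structure(list(
    swept_parameter = name,
    compartment = compartment,
    values = values,
    summaries = purrr::map_dfr(runs, "summary"),
    trajectories = stats::setNames(purrr::map(runs, "traj"),
                                   paste0(name, "=", values)),
    init = init, t_end = t_end
  ), class = "snitr_sweep")
}

#' @export
print.snitr_sweep <- function(x, ...) {
  cat(sprintf("<snitr_sweep>  %s over %d values; compartment %s\n",
              x$swept_parameter, length(x$values), x$compartment))
  print(x$summaries)
  invisible(x)
}

#' Reproduction-number sensitivity grid
#'
#' Evaluates one reproduction number over a 1- or 2-parameter grid
#' (pointwise through [reproduction_numbers()]).
#'
#' @param base_params A [snitr_params()] object.
#' @param target One of `"r01", "r02", "r03"`.
#' @param axes Named list of 1 or 2 numeric grids, e.g.
#'   `list(alpha1 = seq(0.1, 0.6, by = 0.1))`; values must lie in (0, 1).
#' @return A tibble of class `snitr_sensitivity` with one row per grid
#'   point: the axis value column(s) plus the target column.
#' @examples
#' sensitivity_grid(snitr_example_params("rumor_free"), "r01",
#'                  list(alpha1 = seq(0.05, 0.6, by = 0.05)))
#' @export
sensitivity_grid <- function(base_params, target = c("r01", "r02", "r03"),
                             axes) {
  target <- match.arg(target)
  stopifnot(is.list(axes), length(axes) %in% c(1, 2),
            !is.null(names(axes)), all(names(axes) != ""))
  if (any(unlist(axes) <= 0 | unlist(axes) >= 1)) {
    stop("axis values must lie in (0, 1)", call. = FALSE)
  }
  grid <- tidyr::expand_grid(!!!axes)
  vals <- purrr::pmap_dbl(grid, function(...) {
    p <- unclass(base_params)
    upd <- list(...)
    for (nm in names(upd)) p[[nm]] <- upd[[nm]]
    reproduction_numbers(structure(p, class = "snitr_params"))[[target]]
  })
  out <- dplyr::mutate(grid, !!target := vals)
  structure(out, target = target, axes = names(axes),
            class = c("snitr_sensitivity", class(tibble::tibble())))
}

#' Delayed transmitter-entry intervention
#'
#' Simulates debunking that starts only at `t_enter`: on `[0, t_enter)` all
#' transmitter-generating pathways are disabled (`alpha2`, `beta2` and
#' `epsilon` treated as 0); at `t_enter` the pathways are re-enabled and a
#' fraction `seed_fraction` of the susceptible density is moved to the
#' transmitter compartment (total density conserved; the state is otherwise
#' continuous). Peak infected and transmitter densities are measured over
#' the full horizon, and local maxima of the neglected density with at
#' least `prominence` are counted (a second peak after `t_enter` signals
#' rumor resurgence).
#'
#' @param params A [snitr_params()] object.
#' @param t_enter Activation time of the transmitter pathways, `>= 0`.
#' @param seed_fraction Fraction of susceptibles converted at `t_enter`,
#'   in `[0, 0.1]`.
#' @param init Initial condition (5 densities).
#' @param t_end Horizon; must exceed `t_enter`.
#' @param n_points Output grid resolution.
#' @param prominence Minimum height-above-surroundings for a neglected-
#'   density local maximum to count as a peak.
#' @return A list of class `snitr_intervention` with `t_enter`, `max_i`,
#'   `max_t`, `n_peaks`, and the stitched `trajectory`.
#' @export
delayed_transmitter_run <- function(params, t_enter, seed_fraction = 0.01,
                                    init = snitr_default_init(),
                                    t_end = 100, n_points = 800,
                                    prominence = 0.01) {
  stopifnot(t_enter >= 0, seed_fraction >= 0, seed_fraction <= 0.1)
  if (t_enter > t_end) stop("t_enter exceeds t_end", call. = FALSE)
  check_init(init)

  gated <- unclass(params)
  gated[c("alpha2", "beta2", "epsilon")] <- 0
  gated <- structure(gated, class = "snitr_params")

  if (t_enter == 0) {
    state <- init
    traj <- snitr_integrate(params, init = state, t_end = t_end,
                            n_points = n_points)
  } else {
    n1 <- max(2, round(n_points * t_enter / t_end))
    pre <- snitr_integrate(gated, init = init, t_end = t_enter,
                           n_points = n1)
    state <- as.numeric(pre[nrow(pre), c("S", "N", "I", "T", "R")])
    moved <- seed_fraction * state[1]
    state[1] <- state[1] - moved
    state[4] <- state[4] + moved
    state <- state / sum(state)  # guard round-off; move itself conserves
    post <- snitr_integrate(params, init = state, t_end = t_end - t_enter,
                            n_points = n_points - n1)
    post_tbl <- dplyr::mutate(tibble::as_tibble(post),
                              time = .data$time + t_enter)
    traj <- new_snitr_trajectory(
      dplyr::bind_rows(tibble::as_tibble(pre)[-nrow(pre), ], post_tbl),
      params,
      diagnostics = attr(post, "diagnostics")
    )
  }
  peaks <- local_maxima(traj$N, prominence = prominence)
  structure(list(
    t_enter = t_enter, seed_fraction = seed_fraction,
    max_i = max(traj$I), max_t = max(traj$T),
    n_peaks = length(peaks), peak_times = traj$time[peaks],
    trajectory = traj
  ), class = "snitr_intervention")
}

# indices of local maxima of y with prominence >= `prominence`
# (prominence = height above the higher of the two flanking minima)
local_maxima <- function(y, prominence = 0.01) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(y))) < 0) + 1
  keep <- vapply(cand, function(k) {
    left_min <- min(y[1:k])
    right_min <- min(y[k:n])
    y[k] - max(left_min, right_min) >= prominence
  }, logical(1))
  cand[keep]
}

#' @export
print.snitr_intervention <- function(x, ...) {
  cat(sprintf(paste0("<snitr_intervention>  t_enter = %g, seed %.3f: ",
                     "max I %.4f, max T %.4f, %d neglected-density peak(s)\n"),
              x$t_enter, x$seed_fraction, x$max_i, x$max_t, x$n_peaks))
  invisible(x)
}
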