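#' Generate a synthetic binned repost series
#'
#' Emulates the observable the model is fitted to in practice: repost
#' counts of rumor posts aggregated into fixed-width time bins, expressed
#' as an infected-plus-transmitter density. The model is integrated from
#' known parameters, the I+T density is sampled at bin midpoints, and
#' optional count noise is applied:
#' * `"none"` — exact densities;
#' * `"poisson"` — counts drawn with mean `population * density`, rescaled
#'   back to densities (the observation noise of an aggregated repost
#'   count);
#' * `"gaussian"` — zero-mean noise with standard deviation `noise_scale`,
#'   clipped at 0.
#'
#' Defaults mirror a Weibo-style collection: 12,372 reposting users,
#' 10-minute bins over 65 h, the first 30 h forming the fitting window and
#' the remaining 35 h the validation window. Model time is mapped to
#' wall-clock hours 1:1 by default.
#'
#' @param params Generating [snitr_params()]; default the repost case-study
#'   estimates (`snitr_example_params("case_study")`).
#' @param init Initial densities (5 components).
#' @param population User population used to convert densities to counts.
#' @param bin_width Bin width in time units (default 1/6, i.e. 10 minutes).
#' @param duration Total span; windows are set to
#'   `(0, 30/65 * duration, duration)`.
#' @param noise `"none"`, `"poisson"` or `"gaussian"`.
#' @param noise_scale Standard deviation for `"gaussian"` noise.
#' @param seed RNG seed for the noise draws.
#' @param rtol,atol Solver tolerances for the ground-truth integration.
#' @return A tibble of class `snitr_series` with columns `time` (bin
#'   midpoints) and `value` (observed I+T density), and attributes
#'   `bin_width`, `fit_window_end`, `validation_end`, `population`,
#'   `noise`, `seed`, `truth` (the noiseless densities) and `params`.
#' @examples
#' s <- generate_series(duration = 10, noise = "poisson", seed = 7)
#' head(s)
#' @export
generate_series <- function(params = snitr_example_params("case_study"),
                            init = snitr_default_init(),
                            population = 12372, bin_width = 1 / 6,
                            duration = 65,
                            noise = c("none", "poisson", "gaussian"),
                            noise_scale = 0.01, seed = 1,
                            rtol = 1e-8, atol = 1e-10) {
  noise <- match.arg(noise)
  stopifnot(duration > 0, population >= 1, bin_width > 0)
  mids <- seq(bin_width / 2, duration, by = bin_width)
  truth <- model_it_curve(params, init, mids, rtol = rtol, atol = atol)
  values <- switch(noise,
    none = truth,
    poisson = {
      set.seed(seed)
      stats::rpois(length(truth), lambda = population * truth) / population
    },
    gaussian = {
      set.seed(seed)
      pmax(truth + stats::rnorm(length(truth), sd = noise_scale), 0)
    }
  )
  new_snitr_series(
    tibble::tibble(time = mids, value = values),
    bin_width = bin_width,
    fit_window_end = 30 / 65 * duration,
    validation_end = duration,
    population = population,
    noise = noise, seed = seed, truth = truth, params = params
  )
}

# I(t) + T(t) at arbitrary times (single integration)
model_it_curve <- function(params, init, times, rtol = 1e-8, atol = 1e-10) {
  check_init(init)
  tgrid <- sort(unique(c(0, times)))
  deriv <- function(t, y, parms) list(snitr_rhs(y, parms))
  # warnings from abandoned steps are routine during optimisation search;
  # hard failures surface via the row-count check
  sol <- suppressWarnings(
    deSolve::lsoda(y = init, times = tgrid, func = deriv,
                   parms = params, rtol = rtol, atol = atol)
  )
  if (nrow(sol) < length(tgrid) || any(!is.finite(sol))) {
    stop("solver failure while generating the I+T curve", call. = FALSE)
  }
  it <- sol[, 4] + sol[, 5]  # columns: time, S, N, I, T, R
  it[match(times, tgrid)]
}

# like model_it_curve but also returning the 4-state at each time
model_it_curve_states <- function(params, init5, times,
                                  rtol = 1e-7, atol = 1e-9) {
  tgrid <- sort(unique(c(0, times)))
  deriv <- function(t, y, parms) list(snitr_rhs(y, parms))
  sol <- suppressWarnings(
    deSolve::lsoda(y = init5, times = tgrid, func = deriv,
                   parms = params, rtol = rtol, atol = atol)
  )
  if (nrow(sol) < length(tgrid) || any(!is.finite(sol))) {
    stop("solver failure", call. = FALSE)
  }
  idx <- match(times, tgrid)
  states4 <- unname(as.matrix(sol[idx, 2:5, drop = FALSE]))
  list(it = states4[, 3] + states4[, 4],
       states4 = states4,
       end4 = states4[nrow(states4), ])
}

new_snitr_series <- function(tbl, bin_width, fit_window_end, validation_end,
                             population, noise = "none", seed = NA,
                             truth = NULL, params = NULL) {
  if (is.unsorted(tbl$time, strictly = TRUE)) {
    stop("series times must be strictly increasing", call. = FALSE)
  }
  if (any(tbl$value < 0)) stop("series values must be >= 0", call. = FALSE)
  if (!(fit_window_end < validation_end)) {
    stop("fit window must end before the validation window", call. = FALSE)
  }
  structure(tbl, bin_width = bin_width, fit_window_end = fit_window_end,
            validation_end = validation_end, population = population,
            noise = noise, seed = seed, truth = truth, params = params,
            class = c("snitr_series", class(tibble::tibble())))
}

#' @export
print.snitr_series <- function(x, ...) {
  cat(sprintf(paste0("<snitr_series>  %d bins of width %.4g; fit window ",
                     "[0, %g], validation to %g; population %s; noise %s\n"),
              nrow(x), attr(x, "bin_width"), attr(x, "fit_window_end"),
              attr(x, "validation_end"),
              format(attr(x, "population"), big.mark = ","),
              attr(x, "noise")))
  NextMethod()
}

#' Write the canonical fixture files
#'
#' Writes the example parameter sets as flat JSON files plus one noiseless
#' and one Poisson-noise synthetic repost series (generated from the
#' case-study estimates with fixed seeds) into `out_dir`. Regeneration
#' with the same seeds is byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param duration,bin_width Passed to [generate_series()]; the default
#'   fixture series uses 1-hour bins to stay compact.
#' @return Invisibly, the vector of files written.
#' @export
make_fixture_suite <- function(out_dir, duration = 65, bin_width = 1) {
  par_dir <- file.path(out_dir, "params")
  ser_dir <- file.path(out_dir, "series")
  dir.create(par_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(ser_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in snitr_example_names()) {
    f <- file.path(par_dir, paste0(nm, ".json"))
    write_params(snitr_example_params(nm), f)
    files <- c(files, f)
  }
  clean <- generate_series(duration = duration, bin_width = bin_width,
                           noise = "none")
  noisy <- generate_series(duration = duration, bin_width = bin_width,
                           noise = "poisson", seed = 20240901)
  f1 <- file.path(ser_dir, "synthetic_repost_noiseless.csv")
  f2 <- file.path(ser_dir, "synthetic_repost_poisson.csv")
  write_series(clean, f1)
  write_series(noisy, f2)
  invisible(c(files, f1, f2))
}
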