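#' SNITR model parameters
#'
#' Construct and validate the ten transition-rate parameters of the SNITR
#' (Susceptible-Neglected-Infected-Transmitter-Recovered) rumor model.
#'
#' The rates are interpreted per unit model time:
#' * `mu` — user turnover (registration/log-out) rate of the open network;
#' * `alpha1`, `alpha2`, `alpha3` — susceptible contacts converting to
#'   infected, transmitter and neglected nodes respectively;
#' * `beta1`, `beta2`, `beta3` — neglected nodes converting to infected,
#'   transmitter and recovered nodes;
#' * `gamma1` — infected nodes recovering (forgetting);
#' * `gamma2` — transmitter nodes recovering;
#' * `epsilon` — infected nodes switching sides to transmitters.
#'
#' All rates must lie in (0, 1), except `epsilon` which may be exactly 0
#' (a regime with no infected-to-transmitter conversion). Three sum
#' constraints apply: `alpha1 + alpha2 + alpha3 <= 1`,
#' `beta1 + beta2 + beta3 <= 1` and `gamma1 + epsilon <= 1`. With
#' `strict = FALSE` the sum constraints downgrade to warnings, which
#' permits some published sweep configurations that exceed the alpha sum.
#'
#' @param mu,alpha1,alpha2,alpha3,beta1,beta2,beta3,gamma1,gamma2,epsilon
#'   Transition rates, see Details.
#' @param strict Logical; if `TRUE` (default) sum-constraint violations
#'   are errors, otherwise warnings.
#' @return A named numeric vector of class `snitr_params`.
#' @examples
#' p <- snitr_params(mu = 0.28, alpha1 = 0.25, alpha2 = 0.35, alpha3 = 0.28,
#'                   beta1 = 0.3, beta2 = 0.35, beta3 = 0.3,
#'                   gamma1 = 0.3, gamma2 = 0.3, epsilon = 0.3)
#' reproduction_numbers(p)
#' @export
snitr_params <- function(mu, alpha1, alpha2, alpha3,
                         beta1, beta2, beta3,
                         gamma1, gamma2, epsilon,
                         strict = TRUE) {
  p <- c(mu = mu, alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
         beta1 = beta1, beta2 = beta2, beta3 = beta3,
         gamma1 = gamma1, gamma2 = gamma2, epsilon = epsilon)
  validate_snitr_params(p, strict = strict)
  structure(p, class = "snitr_params")
}

#' @rdname snitr_params
#' @param p Named numeric vector with the ten parameter names.
#' @export
validate_snitr_params <- function(p, strict = TRUE) {
  need <- c("mu", "alpha1", "alpha2", "alpha3",
            "beta1", "beta2", "beta3", "gamma1", "gamma2", "epsilon")
  missing_keys <- setdiff(need, names(p))
  if (length(missing_keys) > 0) {
    stop("missing parameter(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  p <- p[need]
  if (any(!is.finite(p))) {
    stop("non-finite parameter(s): ",
         paste(need[!is.finite(p)], collapse = ", "), call. = FALSE)
  }
  # open interval (0,1) for all rates; epsilon = 0 tolerated with a warning
  rng <- need[p <= 0 | p >= 1]
  if ("epsilon" %in% rng && p[["epsilon"]] == 0) {
    warning("epsilon = 0 lies outside the nominal open interval (0, 1); ",
            "accepted as a no-conversion regime", call. = FALSE)
    rng <- setdiff(rng, "epsilon")
  }
  if (length(rng) > 0) {
    stop("parameter(s) outside (0, 1): ", paste(rng, collapse = ", "),
         call. = FALSE)
  }
  sums <- c(
    "alpha1 + alpha2 + alpha3" = p[["alpha1"]] + p[["alpha2"]] + p[["alpha3"]],
    "beta1 + beta2 + beta3"    = p[["beta1"]] + p[["beta2"]] + p[["beta3"]],
    "gamma1 + epsilon"         = p[["gamma1"]] + p[["epsilon"]]
  )
  bad <- sums[sums > 1 + 1e-12]
  if (length(bad) > 0) {
    msg <- paste0("sum constraint violated: ",
                  paste0(names(bad), " = ", signif(bad, 4), " > 1",
                         collapse = "; "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(p)
}

#' @export
print.snitr_params <- function(x, ...) {
  cat("<snitr_params>\n")
  print(round(unclass(x), 6))
  r <- reproduction_numbers(x)
  cat(sprintf("R01 = %.3f  R02 = %.3f  R03 = %.3f  (R0 = %.3f)\n",
              r$r01, r$r02, r$r03, r$r0))
  invisible(x)
}

#' Bundled example parameter sets
#'
#' Named parameter configurations covering each qualitative regime of the
#' model: the rumor-free regime and each boundary/coexistence steady state,
#' the sweep baselines used by the infected- and transmitter-density
#' experiments, and the repost-data least-squares estimates used as the
#' synthetic-data default.
#'
#' @param name One of the names returned by `snitr_example_names()`, or
#'   `NULL` to list them.
#' @return A `snitr_params` object (or a character vector of names).
#' @seealso [snitr_sweep_configs()] for the sweep value grids.
#' @export
snitr_example_params <- function(name = NULL) {
  sets <- snitr_example_sets()
  if (is.null(name)) return(names(sets))
  if (!name %in% names(sets)) {
    stop("unknown example set '", name, "'; available: ",
         paste(names(sets), collapse = ", "), call. = FALSE)
  }
  v <- sets[[name]]
  suppressWarnings(
    snitr_params(mu = v[["mu"]],
                 alpha1 = v[["alpha1"]], alpha2 = v[["alpha2"]],
                 alpha3 = v[["alpha3"]],
                 beta1 = v[["beta1"]], beta2 = v[["beta2"]],
                 beta3 = v[["beta3"]],
                 gamma1 = v[["gamma1"]], gamma2 = v[["gamma2"]],
                 epsilon = v[["epsilon"]], strict = FALSE)
  )
}

#' @rdname snitr_example_params
#' @export
snitr_example_names <- function() names(snitr_example_sets())

# order: mu a1 a2 a3 b1 b2 b3 g1 g2 eps
snitr_example_sets <- function() {
  mk <- function(a1, a2, a3, mu, b1, b2, b3, eps, g1, g2) {
    c(mu = mu, alpha1 = a1, alpha2 = a2, alpha3 = a3,
      beta1 = b1, beta2 = b2, beta3 = b3,
      gamma1 = g1, gamma2 = g2, epsilon = eps)
  }
  list(
    # all three reproduction numbers below 1; converges to (1,0,0,0)
    rumor_free            = mk(0.25, 0.35, 0.28, 0.28, 0.30, 0.35, 0.30, 0.30, 0.30, 0.30),
    # infected-persistent boundary regime (transmitter-free steady state)
    infected_persistent   = mk(0.20, 0.46, 0.25, 0.18, 0.25, 0.30, 0.15, 0.40, 0.15, 0.05),
    # neglected-persistent boundary regime; epsilon = 0
    neglected_persistent  = mk(0.60, 0.18, 0.18, 0.18, 0.50, 0.05, 0.15, 0.00, 0.05, 0.15),
    # transmitter-persistent regime (infection-free steady state)
    transmitter_persistent = mk(0.30, 0.25, 0.38, 0.18, 0.30, 0.30, 0.05, 0.20, 0.15, 0.15),
    # neglected + transmitter coexistence
    neglected_transmitter = mk(0.50, 0.24, 0.24, 0.18, 0.45, 0.20, 0.05, 0.08, 0.05, 0.15),
    # infected + transmitter coexistence
    infected_transmitter  = mk(0.20, 0.36, 0.38, 0.18, 0.20, 0.32, 0.05, 0.08, 0.15, 0.05),
    # full coexistence of N, I and T
    coexistence           = mk(0.46, 0.25, 0.17, 0.18, 0.25, 0.35, 0.05, 0.08, 0.05, 0.05),
    # baselines of the infected-density sweeps (swept rate at range start)
    sweep_I_alpha1        = mk(0.25, 0.15, 0.15, 0.18, 0.25, 0.35, 0.05, 0.08, 0.05, 0.05),
    sweep_I_beta1         = mk(0.55, 0.20, 0.15, 0.18, 0.15, 0.35, 0.05, 0.05, 0.05, 0.05),
    sweep_I_epsilon       = mk(0.55, 0.20, 0.15, 0.18, 0.25, 0.35, 0.05, 0.05, 0.05, 0.05),
    # baselines of the transmitter-density sweeps
    sweep_T_alpha2        = mk(0.15, 0.20, 0.15, 0.18, 0.25, 0.35, 0.05, 0.08, 0.05, 0.05),
    sweep_T_beta2         = mk(0.30, 0.66, 0.38, 0.18, 0.20, 0.15, 0.05, 0.08, 0.15, 0.05),
    sweep_T_epsilon       = mk(0.70, 0.35, 0.20, 0.18, 0.40, 0.20, 0.15, 0.05, 0.05, 0.05),
    # demonstration regime for debunking-timing experiments: strong rumor
    # growth, transmitter spread driven by susceptible contact (small eps)
    intervention_demo     = mk(0.50, 0.45, 0.05, 0.05, 0.20, 0.30, 0.10, 0.05, 0.10, 0.40),
    # least-squares estimates from the Weibo repost case study
    case_study            = mk(0.3553, 0.1168, 0.4315, 0.001, 0.4772, 0.0700,
                               0.2351, 0.0951, 0.4984, 0.0023)
  )
}

#' Sweep configurations for the density experiments
#'
#' The value grids used by the infected-density and transmitter-density
#' parameter sweeps: each entry pairs an example baseline with the name of
#' the swept rate and five evenly spaced values across its range.
#'
#' @return A named list; each element has `base` (name of the example
#'   parameter set), `name` (swept parameter) and `values`.
#' @export
snitr_sweep_configs <- function() {
  list(
    I_alpha1  = list(base = "sweep_I_alpha1",  name = "alpha1",
                     values = seq(0.25, 0.65, by = 0.10), compartment = "I"),
    I_beta1   = list(base = "sweep_I_beta1",   name = "beta1",
                     values = seq(0.15, 0.55, by = 0.10), compartment = "I"),
    I_epsilon = list(base = "sweep_I_epsilon", name = "epsilon",
                     values = seq(0.05, 0.25, by = 0.05), compartment = "I"),
    T_alpha2  = list(base = "sweep_T_alpha2",  name = "alpha2",
                     values = seq(0.20, 0.60, by = 0.10), compartment = "T"),
    T_beta2   = list(base = "sweep_T_beta2",   name = "beta2",
                     values = seq(0.15, 0.35, by = 0.05), compartment = "T"),
    T_epsilon = list(base = "sweep_T_epsilon", name = "epsilon",
                     values = seq(0.05, 0.13, by = 0.02), compartment = "T")
  )
}

#' Read / write parameters as flat JSON
#'
#' The file format is a flat JSON object with the ten keys
#' `mu, alpha1..alpha3, beta1..beta3, gamma1, gamma2, epsilon`.
#'
#' @param path File path.
#' @param strict Passed to [validate_snitr_params()].
#' @return `read_params()` returns a `snitr_params`; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(obj) && !is.numeric(obj)) {
    stop("parameter file must be a flat JSON object", call. = FALSE)
  }
  v <- unlist(obj)
  need <- c("mu", "alpha1", "alpha2", "alpha3",
            "beta1", "beta2", "beta3", "gamma1", "gamma2", "epsilon")
  missing_keys <- setdiff(need, names(v))
  if (length(missing_keys) > 0) {
    stop("missing parameter(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  snitr_params(mu = v[["mu"]],
               alpha1 = v[["alpha1"]], alpha2 = v[["alpha2"]],
               alpha3 = v[["alpha3"]],
               beta1 = v[["beta1"]], beta2 = v[["beta2"]], beta3 = v[["beta3"]],
               gamma1 = v[["gamma1"]], gamma2 = v[["gamma2"]],
               epsilon = v[["epsilon"]], strict = strict)
}

#' @rdname read_params
#' @param params A `snitr_params` object.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(as.list(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
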