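#' SNITR vector field
#'
#' Right-hand side of the five-compartment mean-field ODE system. With
#' densities \eqn{(S, N, I, T, R)} and rates as in [snitr_params()]:
#' \deqn{dS/dt = \mu - \alpha_1 I S - \alpha_2 T S - \alpha_3 S N - \mu S}
#' \deqn{dN/dt = \alpha_3 N S - \beta_1 I N - \beta_2 T N - \beta_3 N - \mu N}
#' \deqn{dI/dt = \alpha_1 S I + \beta_1 N I - (\epsilon + \gamma_1 + \mu) I}
#' \deqn{dT/dt = \alpha_2 S T + \beta_2 N T + \epsilon I - (\gamma_2 + \mu) T}
#' \deqn{dR/dt = \gamma_1 I + \gamma_2 T + \beta_3 N - \mu R}
#' The components sum to \eqn{\mu (1 - S - N - I - T - R)}, so the total
#' density 1 is conserved.
#'
#' @param state Numeric vector `(S, N, I, T, R)` of densities.
#' @param params A [snitr_params()] object (or named numeric vector).
#' @return Numeric vector of the five derivatives.
#' @export
snitr_rhs <- function(state, params) {
  if (length(state) != 5) stop("state must have 5 components", call. = FALSE)
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  p <- as.list(unclass(params))
  s <- state[[1]]; n <- state[[2]]; i <- state[[3]]
  tt <- state[[4]]; r <- state[[5]]
  ds <- p$mu - p$alpha1 * i * s - p$alpha2 * tt * s - p$alpha3 * s * n -
    p$mu * s
  dn <- p$alpha3 * n * s - p$beta1 * i * n - p$beta2 * tt * n -
    p$beta3 * n - p$mu * n
  di <- p$alpha1 * s * i + p$beta1 * n * i -
    (p$epsilon + p$gamma1 + p$mu) * i
  dt_ <- p$alpha2 * s * tt + p$beta2 * n * tt + p$epsilon * i -
    (p$gamma2 + p$mu) * tt
  dr <- p$gamma1 * i + p$gamma2 * tt + p$beta3 * n - p$mu * r
  c(ds, dn, di, dt_, dr)
}

#' Reduced SNITR vector field
#'
#' First four equations of the system; the recovered density decouples and
#' is recoverable as \eqn{R = 1 - (S + N + I + T)} on the invariant simplex.
#'
#' @param state4 Numeric vector `(S, N, I, T)`.
#' @inheritParams snitr_rhs
#' @return Numeric vector of four derivatives.
#' @export
snitr_rhs_reduced <- function(state4, params) {
  if (length(state4) != 4) stop("state must have 4 components", call. = FALSE)
  if (any(!is.finite(state4))) stop("non-finite state", call. = FALSE)
  full <- snitr_rhs(c(state4, 0), params)
  full[1:4]
}

#' Analytic Jacobian of the reduced system
#'
#' Partial derivatives of [snitr_rhs_reduced()] with respect to
#' `(S, N, I, T)`, differentiated from the vector field itself.
#'
#' @param params A [snitr_params()] object.
#' @param point Numeric vector `(S, N, I, T)` at which to evaluate.
#' @return A 4 x 4 numeric matrix.
#' @export
snitr_jacobian <- function(params, point) {
  p <- as.list(unclass(params))
  s <- point[[1]]; n <- point[[2]]; i <- point[[3]]; tt <- point[[4]]
  matrix(c(
    -p$alpha1 * i - p$alpha2 * tt - p$alpha3 * n - p$mu,
    -p$alpha3 * s, -p$alpha1 * s, -p$alpha2 * s,

    p$alpha3 * n,
    p$alpha3 * s - p$beta1 * i - p$beta2 * tt - p$beta3 - p$mu,
    -p$beta1 * n, -p$beta2 * n,

    p$alpha1 * i, p$beta1 * i,
    p$alpha1 * s + p$beta1 * n - p$epsilon - p$gamma1 - p$mu, 0,

    p$alpha2 * tt, p$beta2 * tt, p$epsilon,
    p$alpha2 * s + p$beta2 * n - p$gamma2 - p$mu
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("S", "N", "I", "T"), c("S", "N", "I", "T")))
}

#' Integrate the SNITR system
#'
#' Adaptive-step integration (deSolve's `lsoda`) of the full
#' five-compartment system, sampled on a uniform time grid. The trajectory
#' is checked for density conservation (`|S+N+I+T+R - 1|` below
#' `conservation_tol` at every grid point) and positivity; densities within
#' a small negative round-off band are clipped to `[0, 1]`.
#'
#' @param params A [snitr_params()] object.
#' @param init Numeric vector `(S, N, I, T, R)` of initial densities on the
#'   unit simplex. Default [snitr_default_init()].
#' @param t_end End of the integration interval (model time units).
#' @param n_points Number of output grid points (excluding t = 0).
#' @param rtol,atol Solver tolerances.
#' @param conservation_tol Maximum tolerated drift of the density sum.
#' @param clip_tol Round-off band: densities in `[-clip_tol, 1 + clip_tol]`
#'   are accepted and clipped to `[0, 1]`; larger excursions are an error.
#' @return A tibble of class `snitr_trajectory` with columns
#'   `time, S, N, I, T, R` and attributes `params`, `diagnostics`
#'   (conservation drift, endpoint residual, steady-state flag).
#' @examples
#' p <- snitr_example_params("rumor_free")
#' traj <- snitr_integrate(p, t_end = 50)
#' tail(traj)
#' @export
snitr_integrate <- function(params, init = snitr_default_init(),
                            t_end = 200, n_points = 400,
                            rtol = 1e-8, atol = 1e-10,
                            conservation_tol = 1e-6, clip_tol = 1e-9) {
  stopifnot(t_end > 0, n_points >= 1)
  check_init(init)
  times <- seq(0, t_end, length.out = n_points + 1)
  p <- as.list(unclass(params))
  deriv <- function(t, y, parms) list(snitr_rhs(y, parms))
  sol <- deSolve::lsoda(y = c(S = init[[1]], N = init[[2]], I = init[[3]],
                              T = init[[4]], R = init[[5]]),
                        times = times, func = deriv, parms = params,
                        rtol = rtol, atol = atol)
  diag_ <- attr(sol, "istate")
  if (nrow(sol) < length(times)) {
    stop(sprintf("solver failed near t = %.6g (step-size collapse)",
                 sol[nrow(sol), "time"]), call. = FALSE)
  }
  m <- as.matrix(sol[, c("S", "N", "I", "T", "R")])
  drift <- max(abs(rowSums(m) - 1))
  if (drift >= conservation_tol) {
    stop(sprintf("density conservation drift %.3g exceeds tolerance %.3g",
                 drift, conservation_tol), call. = FALSE)
  }
  if (min(m) < -clip_tol || max(m) > 1 + clip_tol) {
    stop(sprintf("density outside [%.1e, 1 + %.1e]: range [%.3g, %.3g]",
                 clip_tol, clip_tol, min(m), max(m)), call. = FALSE)
  }
  m[m < 0] <- 0
  m[m > 1] <- 1
  end_res <- max(abs(snitr_rhs_reduced(m[nrow(m), 1:4], params)))
  out <- tibble::as_tibble(as.data.frame(cbind(time = times, m)))
  new_snitr_trajectory(out, params,
                       diagnostics = list(conservation_drift = drift,
                                          endpoint_residual = end_res,
                                          steady_state = end_res < 1e-8,
                                          rtol = rtol, atol = atol))
}

new_snitr_trajectory <- function(tbl, params, diagnostics = list()) {
  structure(tbl, params = params, diagnostics = diagnostics,
            class = c("snitr_trajectory", class(tibble::tibble())))
}

#' Default initial condition
#'
#' A simplex-interior starting state with most of the population
#' susceptible and small seeded neglected/infected/transmitter densities:
#' `(S, N, I, T, R) = (0.90, 0.04, 0.04, 0.02, 0)`.
#'
#' @return Named numeric vector of length 5.
#' @export
snitr_default_init <- function() {
  c(S = 0.90, N = 0.04, I = 0.04, T = 0.02, R = 0)
}

check_init <- function(init) {
  if (length(init) != 5 || any(!is.finite(init))) {
    stop("init must be 5 finite densities (S, N, I, T, R)", call. = FALSE)
  }
  if (any(init < 0) || any(init > 1)) {
    stop("init densities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(init) - 1) > 1e-8) {
    stop("init densities must sum to 1", call. = FALSE)
  }
  invisible(init)
}

#' @export
print.snitr_trajectory <- function(x, ...) {
  d <- attr(x, "diagnostics")
  cat(sprintf(paste0("<snitr_trajectory>  %d time points on [0, %g]; ",
                     "conservation drift %.2e; endpoint residual %.2e%s\n"),
              nrow(x), max(x$time), d$conservation_drift,
              d$endpoint_residual,
              if (isTRUE(d$steady_state)) " (steady state)" else ""))
  NextMethod()
}
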