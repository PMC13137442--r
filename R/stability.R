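#' Basic reproduction numbers
#'
#' The three next-generation-matrix reproduction numbers of the model:
#' \deqn{R_{01} = \alpha_1 / (\epsilon + \gamma_1 + \mu)}
#' \deqn{R_{02} = \alpha_2 / (\gamma_2 + \mu)}
#' \deqn{R_{03} = \alpha_3 / (\beta_3 + \mu)}
#' governing the infected, transmitter and neglected invasion thresholds at
#' the rumor-free equilibrium; `r0` is their maximum (the spectral radius
#' of the next-generation matrix).
#'
#' @param params A [snitr_params()] object.
#' @return A one-row tibble with columns `r01, r02, r03, r0`.
#' @examples
#' reproduction_numbers(snitr_example_params("infected_persistent"))
#' @export
reproduction_numbers <- function(params) {
  p <- as.list(unclass(params))
  d1 <- p$epsilon + p$gamma1 + p$mu
  d2 <- p$gamma2 + p$mu
  d3 <- p$beta3 + p$mu
  if (any(c(d1, d2, d3) == 0)) {
    stop("zero denominator in a reproduction number", call. = FALSE)
  }
  r01 <- p$alpha1 / d1
  r02 <- p$alpha2 / d2
  r03 <- p$alpha3 / d3
  tibble::tibble(r01 = r01, r02 = r02, r03 = r03, r0 = max(r01, r02, r03))
}

#' Next-generation matrices at the rumor-free equilibrium
#'
#' New-infection matrix `F`, transition matrix `V` and their product
#' `K = F V^-1`, with the rumor-active compartments ordered (I, T, N).
#' `K` is lower triangular; its diagonal equals the three reproduction
#' numbers, and its single off-diagonal entry
#' \eqn{\alpha_2 \epsilon / ((\epsilon+\gamma_1+\mu)(\gamma_2+\mu))}
#' carries the infected-to-transmitter conversion.
#'
#' @param params A [snitr_params()] object.
#' @return A list with 3 x 3 matrices `f_matrix`, `v_matrix`, `k_matrix`.
#' @export
next_generation_matrices <- function(params) {
  p <- as.list(unclass(params))
  nm <- c("I", "T", "N")
  f_matrix <- diag(c(p$alpha1, p$alpha2, p$alpha3))
  v_matrix <- matrix(c(p$epsilon + p$gamma1 + p$mu, 0, 0,
                       -p$epsilon, p$gamma2 + p$mu, 0,
                       0, 0, p$beta3 + p$mu),
                     nrow = 3, byrow = TRUE)
  dimnames(f_matrix) <- dimnames(v_matrix) <- list(nm, nm)
  if (abs(det(v_matrix)) < 1e-14) {
    stop("transition matrix V is singular", call. = FALSE)
  }
  k_matrix <- f_matrix %*% solve(v_matrix)
  list(f_matrix = f_matrix, v_matrix = v_matrix, k_matrix = k_matrix)
}

#' Routh-Hurwitz determinants of a quartic
#'
#' For the characteristic polynomial
#' \eqn{\lambda^4 + a_3\lambda^3 + a_2\lambda^2 + a_1\lambda + a_0}:
#' \eqn{\Delta_1 = a_3}, \eqn{\Delta_2 = a_3 a_2 - a_1},
#' \eqn{\Delta_3 = a_3 a_2 a_1 - a_3^2 a_0 - a_1^2},
#' \eqn{\Delta_4 = a_0 \Delta_3}. All four positive iff every root has
#' negative real part.
#'
#' @param a3,a2,a1,a0 Real coefficients.
#' @return Named numeric vector `(delta1, delta2, delta3, delta4)`.
#' @export
hurwitz_determinants <- function(a3, a2, a1, a0) {
  stopifnot(is.finite(a3), is.finite(a2), is.finite(a1), is.finite(a0))
  d1 <- a3
  d2 <- a3 * a2 - a1
  d3 <- a3 * a2 * a1 - a3^2 * a0 - a1^2
  d4 <- a0 * d3
  c(delta1 = d1, delta2 = d2, delta3 = d3, delta4 = d4)
}

# monic quartic coefficients (a3, a2, a1, a0) from a real 4x4 matrix,
# via the elementary symmetric functions of its eigenvalues
char_poly_coeffs <- function(J) {
  e <- eigen(J, only.values = TRUE)$values
  a3 <- -Re(sum(e))
  a2 <- Re(sum(e[1] * e[2:4]) + e[2] * e[3] + e[2] * e[4] + e[3] * e[4])
  a1 <- -Re(e[1] * e[2] * e[3] + e[1] * e[2] * e[4] +
              e[1] * e[3] * e[4] + e[2] * e[3] * e[4])
  a0 <- Re(prod(e))
  c(a3 = a3, a2 = a2, a1 = a1, a0 = a0)
}

#' Local stability classification at an equilibrium
#'
#' Evaluates the analytic Jacobian of the reduced system at a point,
#' classifies it from the eigenvalue real parts (with a marginal tolerance
#' band), and cross-checks with the Routh-Hurwitz determinants of the
#' characteristic polynomial. The point must be an equilibrium (residual
#' below `residual_tol`) unless `force = TRUE`.
#'
#' @param params A [snitr_params()] object.
#' @param point `(S, N, I, T)` numeric vector, or the label of a
#'   closed-form candidate (e.g. `"E0"`), or a one-row tibble as returned
#'   by the equilibrium functions.
#' @param force Allow classification at a non-equilibrium point.
#' @param tol Marginal band on eigenvalue real parts.
#' @param residual_tol Maximum `max |rhs|` accepted as an equilibrium.
#' @return An object of class `snitr_stability`: list with `point`,
#'   `jacobian`, `eigenvalues`, `char_poly`, `hurwitz`, `classification`
#'   (`"stable"`, `"unstable"` or `"marginal"`) and `reproduction`.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' classify_stability(snitr_example_params("rumor_free"), "E0")
#' @export
classify_stability <- function(params, point = "E0", force = FALSE,
                               tol = 1e-9, residual_tol = 1e-6) {
  pt <- resolve_point(params, point)
  res <- max(abs(snitr_rhs_reduced(pt, params)))
  if (res > residual_tol && !force) {
    stop(sprintf(paste0("point is not an equilibrium (residual %.3g > %.3g); ",
                        "use force = TRUE to classify anyway"),
                 res, residual_tol), call. = FALSE)
  }
  J <- snitr_jacobian(params, pt)
  ev <- eigen(J, only.values = TRUE)$values
  cp <- char_poly_coeffs(J)
  hw <- hurwitz_determinants(cp[["a3"]], cp[["a2"]], cp[["a1"]], cp[["a0"]])
  mx <- max(Re(ev))
  classification <- if (mx < -tol) "stable" else if (mx > tol) "unstable"
  else "marginal"
  structure(list(point = pt, residual = res, jacobian = J,
                 eigenvalues = ev, char_poly = cp, hurwitz = hw,
                 classification = classification,
                 reproduction = reproduction_numbers(params)),
            class = "snitr_stability")
}

resolve_point <- function(params, point) {
  if (is.character(point)) {
    cf <- closed_form_equilibria(params)
    row <- cf[cf$label == point, ]
    if (nrow(row) != 1 || !row$defined) {
      stop("no defined closed-form point labelled '", point, "'",
           call. = FALSE)
    }
    return(as.numeric(row[, c("S", "N", "I", "T")]))
  }
  if (is.data.frame(point)) {
    return(as.numeric(point[1, c("S", "N", "I", "T")]))
  }
  stopifnot(length(point) == 4)
  as.numeric(point)
}

#' @export
print.snitr_stability <- function(x, ...) {
  cat("<snitr_stability>", x$classification, "\n")
  cat("point     :", paste(sprintf("%.4f", x$point), collapse = " "), "\n")
  cat("eigen Re  :", paste(sprintf("%+.4f", Re(x$eigenvalues)),
                           collapse = " "), "\n")
  cat("hurwitz   :", paste(sprintf("%+.4g", x$hurwitz), collapse = " "), "\n")
  r <- x$reproduction
  cat(sprintf("R01 %.3f  R02 %.3f  R03 %.3f\n", r$r01, r$r02, r$r03))
  invisible(x)
}

#' @method tidy snitr_stability
#' @export
tidy.snitr_stability <- function(x, ...) {
  tibble::tibble(
    eigenvalue = seq_along(x$eigenvalues),
    real = Re(x$eigenvalues),
    imaginary = Im(x$eigenvalues)
  )
}

#' @method glance snitr_stability
#' @export
glance.snitr_stability <- function(x, ...) {
  tibble::tibble(
    classification = x$classification,
    max_re_eigenvalue = max(Re(x$eigenvalues)),
    residual = x$residual,
    delta1 = x$hurwitz[["delta1"]], delta2 = x$hurwitz[["delta2"]],
    delta3 = x$hurwitz[["delta3"]], delta4 = x$hurwitz[["delta4"]],
    r01 = x$reproduction$r01, r02 = x$reproduction$r02,
    r03 = x$reproduction$r03
  )
}

#' Empirical global-convergence check
#'
#' Integrates the system from seeded random simplex-interior starts and
#' reports the fraction that end within `conv_tol` (max-norm) of the
#' rumor-free equilibrium (1, 0, 0, 0). Along each trajectory the
#' quadratic Lyapunov-type energy \eqn{V = (k_0 I^2 + k_1 S^2)/2} is
#' evaluated, and the distance analogue
#' \eqn{W = (k_0 I^2 + k_1 (1-S)^2)/2} is checked for eventual decrease
#' (non-increasing over the final half of the horizon).
#'
#' @param params A [snitr_params()] object.
#' @param n_starts Number of random starts.
#' @param seed RNG seed.
#' @param t_end Integration horizon.
#' @param conv_tol Max-norm radius around the rumor-free state.
#' @param k0,k1 Positive Lyapunov weights.
#' @return A list of class `snitr_global_check` with `fraction`, the
#'   per-start tibble `runs` (start state, endpoint distance, convergence
#'   and eventual-decrease flags), and the settings used.
#' @export
global_convergence_check <- function(params, n_starts = 50, seed = 1,
                                     t_end = 200, conv_tol = 1e-4,
                                     k0 = 1, k1 = 1) {
  stopifnot(n_starts >= 1, k0 > 0, k1 > 0)
  set.seed(seed)
  starts <- t(replicate(n_starts, {
    x <- stats::rexp(5)
    x / sum(x)
  }))
  runs <- purrr::map_dfr(seq_len(n_starts), function(j) {
    init <- starts[j, ]
    traj <- snitr_integrate(params, init = init, t_end = t_end,
                            n_points = 200)
    endpoint <- as.numeric(traj[nrow(traj), c("S", "N", "I", "T")])
    d <- max(abs(endpoint - c(1, 0, 0, 0)))
    w <- (k0 * traj$I^2 + k1 * (1 - traj$S)^2) / 2
    tail_idx <- seq(floor(nrow(traj) / 2), nrow(traj))
    eventually_decreasing <- all(diff(w[tail_idx]) <= 1e-12)
    tibble::tibble(
      start_S = init[1], start_N = init[2], start_I = init[3],
      start_T = init[4], start_R = init[5],
      endpoint_dist = d, converged = d < conv_tol,
      lyapunov_final = (k0 * traj$I[nrow(traj)]^2 +
                          k1 * traj$S[nrow(traj)]^2) / 2,
      eventually_decreasing = eventually_decreasing
    )
  })
  structure(list(fraction = mean(runs$converged), runs = runs,
                 n_starts = n_starts, seed = seed, t_end = t_end,
                 conv_tol = conv_tol, k0 = k0, k1 = k1),
            class = "snitr_global_check")
}

#' @export
print.snitr_global_check <- function(x, ...) {
  cat(sprintf(paste0("<snitr_global_check>  %d starts, t_end = %g: ",
                     "%.0f%% converged to the rumor-free state; ",
                     "distance eventually decreasing in %d/%d runs\n"),
              x$n_starts, x$t_end, 100 * x$fraction,
              sum(x$runs$eventually_decreasing), x$n_starts))
  invisible(x)
}
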