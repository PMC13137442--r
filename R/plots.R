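#' Plot a trajectory
#'
#' Density-evolution curves of all five compartments over time.
#'
#' @param object A `snitr_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snitr_trajectory
#' @export
autoplot.snitr_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("S", "N", "I", "T", "R"),
                              names_to = "compartment",
                              values_to = "density")
  long$compartment <- factor(long$compartment,
                             levels = c("S", "N", "I", "T", "R"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$density,
                                     colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep
#'
#' One density curve of the summarised compartment per swept value.
#'
#' @param object A `snitr_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snitr_sweep
#' @export
autoplot.snitr_sweep <- function(object, ...) {
  long <- purrr::imap_dfr(object$trajectories, function(tr, nm) {
    tibble::tibble(time = tr$time, density = tr[[object$compartment]],
                   value = nm)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$density,
                                     colour = .data$value)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time", y = paste(object$compartment, "density"),
                  colour = object$swept_parameter) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity grid
#'
#' Line plot (one axis) or filled tile map (two axes) of a reproduction
#' number over its parameter grid.
#'
#' @param object A `snitr_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snitr_sensitivity
#' @export
autoplot.snitr_sensitivity <- function(object, ...) {
  target <- attr(object, "target")
  axes <- attr(object, "axes")
  df <- tibble::as_tibble(object)
  if (length(axes) == 1) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]],
                                     y = .data[[target]])) +
      ggplot2::geom_line(linewidth = 0.7) +
      ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]],
                                     y = .data[[axes[2]]],
                                     fill = .data[[target]])) +
      ggplot2::geom_tile() +
      ggplot2::theme_minimal()
  }
}

#' Plot a fit against its observations
#'
#' Observed I+T densities as points, fitted curve as a line, with the end
#' of the fitting window marked.
#'
#' @param object A `snitr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snitr_fit
#' @export
autoplot.snitr_fit <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_point(data = object$observed,
                        ggplot2::aes(x = .data$time, y = .data$value),
                        size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = object$predicted,
                       ggplot2::aes(x = .data$time, y = .data$value),
                       colour = "red", linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = object$fit_window_end,
                        linetype = "dashed") +
    ggplot2::labs(x = "time", y = "I + T density") +
    ggplot2::theme_minimal()
}
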