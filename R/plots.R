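#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an adoption time series
#'
#' Cumulative adopter fraction rho(t) and innovator fraction rho0(t) of a
#' Monte Carlo run, with the frozen-state ceiling 1 - r.
#'
#' @param object An `adoption_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adoption_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(object$series, c("rho", "rho0"),
                            names_to = "series", values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$fraction,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1 - object$pop$r, linetype = 3) +
    ggplot2::labs(x = "iteration (month)", y = "fraction of nodes",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a reduced-AME solution
#'
#' @param object An `ame_reduced` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ame_reduced <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "rho", "nu", "rho0")],
    c("rho", "nu", "rho0"), names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (months)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a crossover scan
#'
#' Final innovator fraction and half-adoption time against the immune
#' fraction, with the located crossover r_c marked.
#'
#' @param object A `crossover_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossover_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curve, c("rho0_inf", "t_c"),
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$r_c, linetype = 2) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "immune fraction r", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a (w, z) adoption phase surface
#'
#' Tile plot of the normalised adoption rho/(1 - r) with the requested
#' contour overlaid.
#'
#' @param object A `phase_surface`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_surface <- function(object, ...) {
  p <- ggplot2::ggplot(object$surface,
                       ggplot2::aes(x = .data$w, y = .data$z)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$rho_norm)) +
    ggplot2::labs(x = "average threshold w", y = "average degree z",
                  fill = expression(rho / (1 - r))) +
    ggplot2::theme_minimal()
  if (nrow(object$contour) > 0)
    p <- p + ggplot2::geom_path(
      data = object$contour,
      ggplot2::aes(x = .data$w, y = .data$z, group = .data$piece),
      colour = "white")
  p
}

#' Plot component-size curves against the immune fraction
#'
#' @param object A `regime_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regime_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("lc", "lc2"),
                            names_to = "statistic", values_to = "size")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$size,
                                   colour = .data$network)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "immune fraction r", y = "relative component size") +
    ggplot2::theme_minimal()
}

#' Scaling collapse of integer-threshold distributions
#'
#' Plots the per-degree-group rescaled distributions k P(Phi_k, k) against
#' Phi_k / k; under the scaling relation the groups fall on one master
#' curve.
#'
#' @param collapsed Output of [collapse_integer_thresholds()].
#' @return A ggplot object.
#' @export
plot_threshold_collapse <- function(collapsed) {
  ggplot2::ggplot(collapsed,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = factor(.data$k))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Phi[k] / k), y = expression(k * P(Phi[k])),
                  colour = "degree group") +
    ggplot2::theme_minimal()
}
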