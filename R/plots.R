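#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot concentration-time profiles of a simulation
#'
#' @param object A `pbk_sim`.
#' @param compartments Compartments to show.
#' @param log_y Use a log10 concentration axis?
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pbk_sim
#' @export
autoplot.pbk_sim <- function(object, compartments = c("blood", "liver"),
                             log_y = FALSE, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$compartment %in% compartments, !is.na(.data$conc_nM))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$conc_nM,
                                        colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$analyte), scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (nM)",
                  colour = "Compartment") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot Monte Carlo quartile bands
#'
#' @param object A `pbk_mc`.
#' @param ... Unused.
#' @return A ggplot with the interquartile ribbon and the median line.
#' @method autoplot pbk_mc
#' @export
autoplot.pbk_mc <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue") +
    ggplot2::labs(
      x = "Time (h)", y = "Concentration (nM)",
      title = sprintf("%s %s, %d Monte Carlo draws (Q1-median-Q3)",
                      object$compartment, object$analyte, object$n_draws)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a kinetic fit with its data
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot of observed rate-substrate pairs and the fitted curve.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  s_grid <- seq(0, max(object$data$s) * 1.05, length.out = 200)
  curve <- tibble::tibble(
    s = s_grid,
    v = if (object$model == "MM") {
      mm_rate(s_grid, object$vmax, object$km)
    } else {
      si_rate(s_grid, object$vmax, object$km, object$ki)
    }
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$s, y = .data$v)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "Substrate (uM)", y = "Rate (nmol/min/mg)",
                  title = sprintf("%s fit, R2 = %.3f", object$model, object$r2)) +
    ggplot2::theme_minimal()
}
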