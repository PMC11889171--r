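#' Plot a damage curve with its decay fit
#'
#' Points with SE error bars against depth-bin midpoint, overlaid with the
#' fitted three-parameter exponential decay.
#'
#' @param points tibble with `x_mid_nm`, a value column and an SE column
#'   (e.g. the `points` element of a [run_depth_profile()] result).
#' @param fit a `decay_fit`.
#' @param value,se column names of value and SE (default the resolution
#'   difference curve).
#' @param ylab y-axis label.
#' @return a ggplot object.
#' @export
plot_damage_curve <- function(points, fit, value = "dres_A",
                              se = "dres_se",
                              ylab = "extrapolated resolution difference (Å)") {
  df <- data.frame(x = points$x_mid_nm, y = points[[value]],
                   se = points[[se]])
  curve <- data.frame(x = seq(min(df$x), max(df$x), length.out = 200))
  curve$y <- fit$A * exp(-fit$k * curve$x) + fit$c
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y - .data$se,
                                        ymax = .data$y + .data$se),
                           width = 1) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(
      x = "distance from milling surface (nm)", y = ylab,
      subtitle = sprintf("y = %.3g e^{-%.3g x} + %.3g   (R² = %.2f)",
                         fit$A, fit$k, fit$c, fit$r_squared)) +
    ggplot2::theme_minimal()
}

#' Rosenthal-Henderson plot for a resolution series
#'
#' `1/resolution^2` against `ln(particle number)` with the pooled OLS line.
#'
#' @param series a [resolution_series()].
#' @param fit optional `linear_fit`; computed from the series if missing.
#' @return a ggplot object.
#' @export
plot_rh_series <- function(series, fit = NULL) {
  fit <- fit %||% rh_fit(series)
  df <- data.frame(x = log(series$n_particles),
                   y = 1 / series$resolution_A^2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "ln(particle number)",
                  y = expression(1 / resolution^2 ~ (ring(A)^-2)),
                  subtitle = sprintf("B = %.0f Å²",
                                     2 / fit$slope)) +
    ggplot2::theme_minimal()
}
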