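#' Predicted balance activity time across temperature
#'
#' Draws the energetics model's minimum daily activity time as a function of
#' ambient temperature for a reference individual, optionally overlaying
#' observed individual-days. The curve is flat within the thermoneutral zone
#' and rises as temperature falls below the lower critical temperature until
#' balance becomes infeasible (capped at 24 h, dashed).
#'
#' @param p A [species_params()] object.
#' @param M Reference body mass, kg.
#' @param Ta_range Temperature range to draw, degC.
#' @param observed Optional tibble with `Ta` and `t_obs` columns.
#' @return A ggplot object.
#' @export
plot_activity_model <- function(p, M, Ta_range = c(-40, 10), observed = NULL) {
  stopifnot(inherits(p, "species_params"))
  grid <- required_activity_time(seq(Ta_range[1], Ta_range[2], length.out = 400), M, p)
  gg <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$Ta, y = .data$t_pred)) +
    ggplot2::geom_line(ggplot2::aes(linetype = !.data$feasible), linewidth = 0.8,
                       show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = p$TLC, linetype = 3, colour = "grey40") +
    ggplot2::labs(
      x = "Mean daily temperature (°C)",
      y = "Daily activity time for energy balance (h)",
      title = sprintf("%s, %.2f kg", p$species_name, M)
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 24)) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    gg <- gg + ggplot2::geom_point(
      data = observed, ggplot2::aes(x = .data$Ta, y = .data$t_obs),
      alpha = 0.3, colour = "steelblue", inherit.aes = FALSE
    )
  }
  gg
}

#' Coefficient plot for a fitted deviation model
#'
#' Fixed-effect estimates with Wald confidence intervals, one row per term
#' (intercept omitted by default). On a standardized fit the x-axis is hours
#' of activity deviation per SD of each covariate.
#'
#' @param object A `deviation_lmm` object.
#' @param drop_intercept Omit the intercept row.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deviation_lmm
#' @export
autoplot.deviation_lmm <- function(object, drop_intercept = TRUE, ...) {
  d <- object$fixed
  if (drop_intercept) d <- dplyr::filter(d, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high)) +
    ggplot2::labs(x = "Effect on activity deviation (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Same-day activity synchrony scatter
#'
#' Plots every same-day pair of individuals (one point per unordered pair)
#' with a linear trend; the pooled Pearson correlation is shown in the
#' subtitle.
#'
#' @param records Activity tibble (`individual_id`, `date`, `t_obs`).
#' @inheritParams enumerate_same_day_pairs
#' @return A ggplot object.
#' @export
plot_synchrony <- function(records, pair_ordering = "single") {
  pairs <- enumerate_same_day_pairs(records, pair_ordering)
  r <- interindividual_synchrony(records, pair_ordering)
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$x_a, y = .data$x_b)) +
    ggplot2::geom_point(alpha = 0.25) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick") +
    ggplot2::labs(
      x = "Daily activity of individual A (h)",
      y = "Daily activity of individual B (h)",
      subtitle = sprintf("pooled same-day pairs, r = %.2f", r)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
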