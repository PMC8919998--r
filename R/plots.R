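#' Plot model cost curves over speed by load
#'
#' Draws the predicted metabolic rate against walking speed for a set of
#' backpack loads, the standard way this model family is visualised.
#'
#' @param coefficients A [backpack_coefficients()] set.
#' @param m_rest Resting metabolic rate to include, W·kg⁻¹.
#' @param load_fractions Loads to draw, fractions of body mass.
#' @param speeds Speed grid, m·s⁻¹.
#' @return A ggplot object.
#' @export
#' @examples
#' plot_cost_curves()
plot_cost_curves <- function(coefficients = lcda_backpacking_coefficients(),
                             m_rest = 1.1,
                             load_fractions = c(0, 0.22, 0.44, 0.66),
                             speeds = seq(0, 1.97, by = 0.01)) {
  grid <- tidyr::expand_grid(load_fraction = load_fractions,
                             speed_mps = speeds)
  grid$m_wkg <- predict_metabolic_rate(
    m_rest = m_rest, speed = grid$speed_mps,
    load_fraction = grid$load_fraction, coefficients = coefficients
  )
  grid$load <- factor(sprintf("%d%% body mass", round(100 * grid$load_fraction)),
                      levels = sprintf("%d%% body mass",
                                       round(100 * sort(load_fractions))))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$speed_mps, y = .data$m_wkg,
                                     colour = .data$load)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Walking speed (m/s)",
                  y = "Metabolic rate (W/kg body mass)",
                  colour = "Backpack load") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_backpacking_model Observed versus fitted metabolic rates
#'   with the identity line.
#' @param object A `ruckmet_fit`.
#' @param ... Unused.
#' @export
autoplot.ruckmet_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$.fitted, y = .data$m_wkg)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.5,
                        ggplot2::aes(colour = factor(.data$load_fraction))) +
    ggplot2::labs(x = "Fitted metabolic rate (W/kg)",
                  y = "Observed metabolic rate (W/kg)",
                  colour = "Load fraction") +
    ggplot2::theme_minimal()
}

#' @describeIn validate_predictions Paired differences against measured
#'   rates with the bias, its 90% interval, and the equivalence limits.
#' @param object A `ruckmet_validation` object.
#' @export
autoplot.ruckmet_validation <- function(object, ...) {
  d <- object$pairs
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measured, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$equivalence_limit,
                        linetype = "dotted", colour = "firebrick") +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$ci90[["low"]], ymax = object$ci90[["high"]],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::labs(x = "Measured metabolic rate (W/kg)",
                  y = "Predicted - measured (W/kg)") +
    ggplot2::theme_minimal()
}

#' @describeIn cross_validate Per-fold bias with bootstrap 90% intervals
#'   and the pooled equivalence limits.
#' @param object A `ruckmet_cv` object.
#' @param ... Unused.
#' @export
autoplot.ruckmet_cv <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fold, y = .data$bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(
      yintercept = c(-1, 1) * object$pooled$equivalence_limit,
      linetype = "dotted", colour = "firebrick"
    ) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci90_low,
                                          ymax = .data$ci90_high)) +
    ggplot2::labs(x = "Fold", y = "Bias (W/kg), 90% bootstrap CI") +
    ggplot2::theme_minimal()
}
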