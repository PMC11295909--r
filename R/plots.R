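#' Plot predicted and observed cooperation curves
#'
#' Point estimates with 95% interval bars per round, one colour per
#' source, mirroring the simulation-versus-data comparison figure.
#'
#' @param object A `cooperation_curve` (rows from one or both sources
#'   may be bound together).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cooperation_curve
#' @export
autoplot.cooperation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$round, y = .data$point,
                                       colour = .data$source)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           width = 0.3,
                           position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.5)) +
    ggplot2::scale_colour_manual(values = c(simulated = "black",
                                            observed = "grey55")) +
    ggplot2::labs(x = "Round", y = "Proportion of full cooperation",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a placebo battery against the focal estimate
#'
#' Each placebo set's point estimate and 95% CI, ordered by estimate,
#' with the focal prime-indicator estimate and its CI as vertical lines.
#'
#' @param battery Output of [run_battery()].
#' @param focal The focal `coop_fit`.
#' @return A ggplot object.
#' @export
plot_battery <- function(battery, focal) {
  fr <- coef_row(focal, "indicator")
  df <- battery[order(battery$estimate), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$rank)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ci_lower,
                                       xend = .data$ci_upper,
                                       yend = .data$rank,
                                       colour = .data$scheme),
                          alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate), size = 0.4,
                        colour = "navy") +
    ggplot2::geom_vline(xintercept = fr$estimate) +
    ggplot2::geom_vline(xintercept = c(fr$ci_lower, fr$ci_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Placebo indicator coefficient", y = "Placebo set",
                  colour = "Scheme") +
    ggplot2::theme_minimal()
}

#' Plot the distance-coefficient association
#'
#' Scatter of placebo-set Euclidean distance from the primes against the
#' estimated placebo indicator coefficient.
#'
#' @param battery Output of [run_battery()].
#' @return A ggplot object.
#' @export
plot_distance_association <- function(battery) {
  ggplot2::ggplot(battery,
                  ggplot2::aes(x = .data$distance_to_primes,
                               y = .data$estimate,
                               colour = .data$scheme)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Euclidean distance from the primes",
                  y = "Placebo indicator coefficient",
                  colour = "Scheme") +
    ggplot2::theme_minimal()
}
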