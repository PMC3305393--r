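# ggplot2 methods for the package's result types

#' Plot expected-regret decision curves
#'
#' Draws the three strategies' expected regret against the threshold
#' probability, optionally marking the minimum-regret strategy along the
#' bottom of the panel.
#'
#' @param object A `regret_dca` table from [decision_curves()].
#' @param show_optimal Mark the per-threshold optimal strategy?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regret_dca
#' @export
autoplot.regret_dca <- function(object, show_optimal = TRUE, ...) {
  long <- tidy(object)
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$pt, y = .data$expected_regret,
                                    colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(
      x = "threshold probability",
      y = "expected regret (scaled)",
      colour = "strategy",
      title = "Regret-based decision curves for hospice referral",
      subtitle = sprintf("n = %d, prevalence = %.2f", attr(object, "n"),
                         attr(object, "prevalence"))
    ) +
    ggplot2::theme_minimal()
  if (show_optimal) {
    marks <- dplyr::distinct(long, .data$pt, .data$optimal)
    p <- p + ggplot2::geom_rug(
      data = marks,
      ggplot2::aes(x = .data$pt, colour = .data$optimal),
      inherit.aes = FALSE, sides = "b", length = ggplot2::unit(0.03, "npc")
    )
  }
  p
}

#' @rdname autoplot.regret_dca
#' @param curves A `regret_dca` table.
#' @export
plot_decision_curves <- function(curves, show_optimal = TRUE) {
  autoplot(curves, show_optimal = show_optimal)
}

#' Plot the risk distribution of a synthetic cohort
#'
#' Histogram of predicted death probabilities split by observed outcome,
#' annotated with the empirical AUC and prevalence.
#'
#' @param object A `regret_cohort` from [generate_cohort()].
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regret_cohort
#' @export
autoplot.regret_cohort <- function(object, bins = 40, ...) {
  g <- glance(object)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$p, fill = .data$died)) +
    ggplot2::geom_histogram(bins = bins, position = "identity",
                            alpha = 0.55) +
    ggplot2::labs(
      x = "predicted death probability",
      y = "patients",
      fill = "died within 180 days",
      title = "Synthetic prediction cohort",
      subtitle = sprintf("n = %d, prevalence = %.3f, AUC = %.3f",
                         g$n, g$prevalence, g$auc)
    ) +
    ggplot2::theme_minimal()
}
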