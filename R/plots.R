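#' Plot predicted versus chronological age
#'
#' Scatter of predicted against chronological age with the identity line
#' (dashed) and the least-squares fit (solid); the gap between the two lines
#' is what the MAB metric summarises. Replicate pairs, when present in
#' `replicate_group`, are connected by vertical segments.
#'
#' @param predictions Tibble with `age` and `predicted_age` (e.g. from
#'   [cross_validate()]), optionally `replicate_group`.
#' @return A ggplot object.
#' @export
plot_predictions <- function(predictions) {
  p <- ggplot2::ggplot(predictions,
                       ggplot2::aes(x = .data$age, y = .data$predicted_age)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "orange", linewidth = 0.8) +
    ggplot2::labs(x = "Chronological age (years)",
                  y = "Predicted age (years)")
  if ("replicate_group" %in% names(predictions) &&
      any(!is.na(predictions$replicate_group))) {
    reps <- predictions[!is.na(predictions$replicate_group), ]
    p <- p + ggplot2::geom_line(
      data = reps,
      ggplot2::aes(group = .data$replicate_group),
      colour = "gold", alpha = 0.7
    )
  }
  p
}

#' @describeIn binned_profile Histogram of per-CpG trajectory correlations.
#' @param object A `bin_profile`.
#' @param ... Unused.
#' @export
autoplot.bin_profile <- function(object, ...) {
  ggplot2::ggplot(object$correlations, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey30") +
    ggplot2::labs(
      x = sprintf("Pearson r of per-bin %s vs age-bin midpoint", object$statistic),
      y = "CpGs"
    )
}

#' @describeIn delta_age_model Coefficient plot with BH significance.
#' @param object A `delta_age_fit`.
#' @param q_cutoff FDR threshold for highlighting (default 0.05).
#' @param ... Unused.
#' @export
autoplot.delta_age_fit <- function(object, q_cutoff = 0.05, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      significant = .data$q_value < q_cutoff)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$variable, .data$estimate),
                                   y = .data$estimate,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - 1.96 * .data$std_error,
                                        ymax = .data$estimate + 1.96 * .data$std_error),
                           width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Delta-age coefficient (years)",
                  fill = sprintf("FDR < %.2g", q_cutoff))
}

#' @describeIn build_ensemble Score-vs-weight plot of the retained models.
#' @param object An `ensemble_clock`.
#' @param ... Unused.
#' @export
autoplot.ensemble_clock <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total_score,
                                   y = .data$ensemble_weight)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Model total score (lower is better)",
                  y = "Ensemble weight")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
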