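#' Plot the ROC curve of an evaluation report
#'
#' @param object An `eval_report` (one row).
#' @param ... Unused.
#' @return A ggplot object: the ROC curve with the chance diagonal and the
#'   AUC in the subtitle.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  roc <- object$roc[[1L]]
  title <- if ("model_id" %in% names(object)) object$model_id[1L] else
    "classifier"
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = paste("ROC -", title),
                  subtitle = sprintf("AUC = %.2f%%", object$auc[1L])) +
    ggplot2::theme_minimal()
}

#' Plot TOPSIS closeness scores
#'
#' @param object A `topsis_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of closeness by model, ordered by rank.
#' @exportS3Method ggplot2::autoplot
autoplot.topsis_result <- function(object, ...) {
  d <- tidy(object)
  d$model_id <- factor(d$model_id, levels = rev(d$model_id[order(d$rank)]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$closeness,
                                  y = .data$model_id)) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::labs(x = "TOPSIS closeness", y = NULL,
                  title = "Multi-criteria model ranking") +
    ggplot2::theme_minimal()
}

#' Grouped bar chart comparing models across the eight metrics
#'
#' @param metrics A tibble with `model_id` and the eight metric columns on
#'   the percent scale (e.g. the pipeline's `model_metrics.csv` or
#'   [published_model_metrics()]).
#' @return A ggplot object.
#' @export
plot_metric_comparison <- function(metrics) {
  long <- tidyr::pivot_longer(metrics, -"model_id", names_to = "metric",
                              values_to = "value")
  long$metric <- factor(long$metric, levels = topsis_criteria()$name)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model_id, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Percent", fill = "Metric") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
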