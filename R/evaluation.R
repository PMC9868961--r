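#' Confusion-matrix counts at a score threshold
#'
#' A score at or above the threshold calls the site positive (on-target).
#'
#' @param labels Binary vector (0/1).
#' @param scores Numeric score vector, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0L) abort("empty input")
  if (length(labels) != length(scores)) {
    abort("labels and scores must have equal length")
  }
  if (!all(labels %in% c(0, 1))) abort("labels must be binary 0/1")
  pos <- scores >= threshold
  tibble(tp = sum(labels == 1 & pos), fp = sum(labels == 0 & pos),
         tn = sum(labels == 0 & !pos), fn = sum(labels == 1 & !pos))
}

#' F-beta score
#'
#' The weighted harmonic mean of precision and recall,
#' \eqn{(1+\beta^2) P R / (\beta^2 P + R)}. Beta = 1 weighs them equally;
#' beta = 2 weighs recall four times as much as precision.
#'
#' @param precision,recall Proportions in \[0, 1\] (not percentages).
#' @param beta Positive weight on recall.
#' @return The F-beta score as a proportion.
#' @examples
#' f_beta(0.9475, 0.9856, 1)   # ~0.9662
#' f_beta(0.9475, 0.9856, 2)   # ~0.9777
#' @export
f_beta <- function(precision, recall, beta = 1) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1)) {
    abort("precision and recall must lie in [0, 1]")
  }
  if (any(precision == 0 & recall == 0)) {
    abort("F-beta is undefined when precision and recall are both 0")
  }
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the distinct score values from high
#' to low; tied scores move together (the standard convention, which makes
#' the trapezoidal area equal the Mann-Whitney rank statistic with tie
#' correction). The curve starts at (0, 0) and ends at (1, 1) and is
#' non-decreasing in both coordinates.
#'
#' @param labels Binary vector with both classes present.
#' @param scores Numeric score vector.
#' @return A tibble of ordered `fpr`, `tpr` points.
#' @export
roc_points <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    abort("labels and scores must have equal length")
  }
  if (!all(labels %in% c(0, 1))) abort("labels must be binary 0/1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    abort("ROC requires both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # group tied scores: cumulative counts at each distinct-score boundary
  last_of_group <- c(sc[-length(sc)] != sc[-1L], TRUE)
  cum_tp <- cumsum(lab == 1)[last_of_group]
  cum_fp <- cumsum(lab == 0)[last_of_group]
  tibble(fpr = c(0, cum_fp / n_neg), tpr = c(0, cum_tp / n_pos))
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of the ROC curve; with grouped ties this equals the
#' Mann-Whitney statistic (concordant pairs + half the tied pairs, over
#' all positive-negative pairs).
#'
#' @param labels,scores As in [roc_points()], or pass a precomputed points
#'   tibble via `points`.
#' @param points Optional tibble of (`fpr`, `tpr`) points.
#' @return AUC as a proportion in \[0, 1\].
#' @export
auc_score <- function(labels = NULL, scores = NULL, points = NULL) {
  if (is.null(points)) points <- roc_points(labels, scores)
  sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
}

#' The eight-metric evaluation suite
#'
#' Computes accuracy, precision, recall (sensitivity), false-positive rate,
#' specificity, F1, F2 and AUC for one set of scored sites, all reported as
#' percentages (full precision internally; round for display). Specificity
#' is 100 minus the FPR by construction. A ratio with a zero denominator is
#' reported as `NA` with a warning, never silently as 0.
#'
#' @param labels Binary vector (0/1).
#' @param scores Numeric scores in \[0, 1\].
#' @param threshold Decision threshold for the confusion matrix
#'   (default 0.5); AUC uses the raw scores.
#' @return An object of class `eval_report`: a one-row tibble with the
#'   eight metric columns (percent scale) plus list-columns `counts` and
#'   `roc`.
#' @examples
#' metric_suite(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))
#' @export
metric_suite <- function(labels, scores, threshold = 0.5) {
  cts <- confusion_counts(labels, scores, threshold)
  n <- cts$tp + cts$fp + cts$tn + cts$fn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, " undefined (zero denominator); reported as NA"))
      return(NA_real_)
    }
    num / den
  }
  accuracy <- (cts$tp + cts$tn) / n
  precision <- ratio(cts$tp, cts$tp + cts$fp, "precision")
  recall <- ratio(cts$tp, cts$tp + cts$fn, "recall")
  fpr <- ratio(cts$fp, cts$fp + cts$tn, "FPR")
  specificity <- if (is.na(fpr)) NA_real_ else 1 - fpr
  f1 <- if (isTRUE(precision == 0 && recall == 0) || is.na(precision) ||
            is.na(recall)) NA_real_ else f_beta(precision, recall, 1)
  f2 <- if (isTRUE(precision == 0 && recall == 0) || is.na(precision) ||
            is.na(recall)) NA_real_ else f_beta(precision, recall, 2)
  roc <- roc_points(labels, scores)
  auc <- auc_score(points = roc)
  out <- tibble(accuracy = 100 * accuracy, precision = 100 * precision,
                recall = 100 * recall, fpr = 100 * fpr,
                specificity = 100 * specificity, f1 = 100 * f1,
                f2 = 100 * f2, auc = 100 * auc,
                counts = list(cts), roc = list(roc))
  class(out) <- c("eval_report", class(out))
  out
}

#' Evaluate a fitted model on a labeled feature table
#'
#' Scores the rows with [predict_scores()] and runs [metric_suite()],
#' attaching model and surface provenance.
#'
#' @param model A `cleavage_model`.
#' @param data A featurized tibble including `label`.
#' @param threshold Decision threshold (default 0.5).
#' @param surface Provenance tag for the report (e.g. `"holdout"`).
#' @return A one-row `eval_report` tibble with `model_id`, `surface`, `n`
#'   prepended.
#' @export
evaluate_model <- function(model, data, threshold = 0.5,
                           surface = "holdout") {
  scores <- predict_scores(model, data)
  rep <- metric_suite(data$label, scores, threshold = threshold)
  mutate(rep, model_id = model$config$model_id, surface = surface,
         n = nrow(data), .before = 1L)
}

#' Mean of per-fold cross-validation reports
#'
#' Averages the eight metrics over the fold reports of [cross_validate()]
#' (the `cv_mean` surface); the pooled out-of-fold predictions can instead
#' be evaluated directly with [metric_suite()] (the `cv_pooled` surface).
#'
#' @param fold_reports The `folds` tibble from [cross_validate()].
#' @return A one-row tibble of averaged metrics with surface `"cv_mean"`.
#' @export
cv_mean_report <- function(fold_reports) {
  metrics <- c("accuracy", "precision", "recall", "fpr", "specificity",
               "f1", "f2", "auc")
  out <- summarise(fold_reports,
                   across(all_of(metrics), ~ mean(.x, na.rm = TRUE)))
  mutate(out, model_id = fold_reports$model_id[1L], surface = "cv_mean",
         n = sum(fold_reports$n), .before = 1L)
}
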