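#' Tidy a fitted cleavage model
#'
#' Returns the hyperparameters of the fitted configuration, one row per
#' term, in broom style.
#'
#' @param x A `cleavage_model`.
#' @param ... Unused.
#' @return A tibble with `term` and `value` (character-encoded).
#' @exportS3Method generics::tidy
tidy.cleavage_model <- function(x, ...) {
  p <- x$config$params[[1L]]
  tibble(term = names(p),
         value = map_chr(p, function(v) paste(v, collapse = ":")))
}

#' One-row summary of a fitted cleavage model
#'
#' @param x A `cleavage_model`.
#' @param ... Unused.
#' @return A one-row tibble: `model_id`, `family`, `n_train`,
#'   `n_features`, `standardized`, `seed`, and for perceptrons the number
#'   of training epochs run.
#' @exportS3Method generics::glance
glance.cleavage_model <- function(x, ...) {
  tibble(model_id = x$config$model_id, family = x$config$family,
         n_train = x$n_train, n_features = length(x$feature_names),
         standardized = !is.null(x$scaler), seed = x$seed,
         epochs = if (x$config$family == "ANN") x$fit$epochs else
           NA_integer_)
}

#' Tidy an evaluation report
#'
#' Pivots the eight metrics to long form, one metric per row.
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with `metric` and `value` (percent scale), preceded by
#'   any provenance columns present.
#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  metrics <- c("accuracy", "precision", "recall", "fpr", "specificity",
               "f1", "f2", "auc")
  keep <- intersect(c("model_id", "surface", "n"), names(x))
  tidyr::pivot_longer(select(as_tibble(x), all_of(c(keep, metrics))),
                      all_of(metrics), names_to = "metric",
                      values_to = "value")
}

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A one-row tibble of the eight metrics plus the confusion counts.
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  bind_cols(select(as_tibble(x), -"counts", -"roc"), x$counts[[1L]])
}

#' Tidy a TOPSIS result
#'
#' @param x A `topsis_result`.
#' @param ... Unused.
#' @return The underlying tibble (`model_id`, `closeness`, `rank`).
#' @exportS3Method generics::tidy
tidy.topsis_result <- function(x, ...) {
  as_tibble(unclass(x)[c("model_id", "closeness", "rank")])
}

#' One-row summary of a TOPSIS result
#'
#' @param x A `topsis_result`.
#' @param ... Unused.
#' @return A one-row tibble: number of alternatives, the winner and its
#'   closeness, and the normalization used.
#' @exportS3Method generics::glance
glance.topsis_result <- function(x, ...) {
  tibble(n_alternatives = nrow(x), best = x$model_id[x$rank == 1L],
         best_closeness = x$closeness[x$rank == 1L],
         normalization = attr(x, "normalization") %||% "vector")
}
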