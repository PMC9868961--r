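#' Default TOPSIS criteria for model ranking
#'
#' The eight evaluation metrics with equal weights (1/8). The
#' false-positive rate is a cost criterion (lower is better); every other
#' metric is a benefit.
#'
#' @return A tibble: `name`, `direction` (`benefit`/`cost`), `weight`.
#' @export
topsis_criteria <- function() {
  nm <- c("accuracy", "precision", "recall", "fpr", "specificity", "f1",
          "f2", "auc")
  tibble(name = nm,
         direction = ifelse(nm == "fpr", "cost", "benefit"),
         weight = 1 / length(nm))
}

#' Build a TOPSIS decision matrix from model reports
#'
#' Rows are models in report order; columns are the criteria, on the
#' percentage scale the reports use. Weights are normalized to sum to 1.
#'
#' @param reports A data frame with a `model_id` column and one column per
#'   criterion (e.g. the metric table written by the pipeline, or the
#'   published reference table from [published_model_metrics()]).
#' @param criteria A criteria tibble as from [topsis_criteria()].
#' @return An object of class `decision_matrix`: list with `alternatives`,
#'   `criteria` and the numeric `values` matrix.
#' @export
build_decision_matrix <- function(reports, criteria = topsis_criteria()) {
  reports <- as_tibble(reports)
  if (nrow(reports) < 2L) {
    abort("TOPSIS needs at least 2 alternatives")
  }
  missing_cols <- setdiff(criteria$name, names(reports))
  if (length(missing_cols)) {
    abort(paste0("reports are missing criterion column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  vals <- as.matrix(reports[, criteria$name])
  if (!all(is.finite(vals))) {
    abort("decision matrix contains non-finite values")
  }
  rownames(vals) <- reports$model_id
  criteria$weight <- criteria$weight / sum(criteria$weight)
  structure(list(alternatives = reports$model_id, criteria = criteria,
                 values = vals),
            class = "decision_matrix")
}

#' TOPSIS closeness scores
#'
#' Classical Hwang-Yoon TOPSIS: each criterion column is normalized (by
#' default to unit Euclidean norm), weighted, and compared against the
#' ideal point (per-column best: maximum for benefit criteria, minimum for
#' cost) and the anti-ideal point (per-column worst). The closeness
#' coefficient is \eqn{C = S^- / (S^+ + S^-)}, the relative Euclidean
#' distance from the anti-ideal; an alternative identical to the ideal
#' scores 1, identical to the anti-ideal scores 0. Under vector
#' normalization the closeness is invariant to rescaling any criterion by
#' a positive constant.
#'
#' @param matrix A `decision_matrix` from [build_decision_matrix()].
#' @param normalization `"vector"` (x over the column Euclidean norm, the
#'   classical choice and the default) or `"minmax"` (linear rescaling of
#'   each column to \[0, 1\], with cost columns inverted).
#' @return An object of class `topsis_result`: a tibble `model_id`,
#'   `closeness`, `rank` ordered by descending closeness, ties broken by
#'   `model_id`.
#' @export
topsis_scores <- function(matrix, normalization = c("vector", "minmax")) {
  stopifnot(inherits(matrix, "decision_matrix"))
  normalization <- match.arg(normalization)
  X <- matrix$values
  cost <- matrix$criteria$direction == "cost"
  w <- matrix$criteria$weight
  if (normalization == "vector") {
    norms <- sqrt(colSums(X^2))
    if (any(norms == 0)) {
      abort("all-zero criterion column: vector normalization undefined")
    }
    R <- sweep(X, 2L, norms, "/")
    cost_eff <- cost
  } else {
    rng <- apply(X, 2L, function(x) max(x) - min(x))
    if (any(rng == 0)) {
      abort("constant criterion column: min-max normalization undefined")
    }
    R <- vapply(seq_len(ncol(X)), function(j) {
      x <- X[, j]
      if (cost[j]) (max(x) - x) / rng[j] else (x - min(x)) / rng[j]
    }, numeric(nrow(X)))
    cost_eff <- rep(FALSE, ncol(X))   # inversion folded into normalization
  }
  V <- sweep(R, 2L, w, "*")
  ideal <- vapply(seq_len(ncol(V)), function(j) {
    if (cost_eff[j]) min(V[, j]) else max(V[, j])
  }, numeric(1))
  anti <- vapply(seq_len(ncol(V)), function(j) {
    if (cost_eff[j]) max(V[, j]) else min(V[, j])
  }, numeric(1))
  s_plus <- sqrt(rowSums(sweep(V, 2L, ideal)^2))
  s_minus <- sqrt(rowSums(sweep(V, 2L, anti)^2))
  closeness <- s_minus / (s_plus + s_minus)
  res <- tibble(model_id = matrix$alternatives,
                closeness = unname(closeness))
  res <- topsis_rank(res)
  attr(res, "normalization") <- normalization
  class(res) <- c("topsis_result", class(res))
  res
}

#' Rank alternatives by descending closeness
#'
#' @param results A tibble with `model_id` and `closeness`.
#' @return The tibble ordered by descending closeness with a `rank` column
#'   (1 = best); ties are broken deterministically by `model_id`.
#' @export
topsis_rank <- function(results) {
  out <- arrange(results, desc(.data$closeness), .data$model_id)
  mutate(out, rank = row_number())
}

#' Sweep TOPSIS variants against a reference ranking
#'
#' Runs every combination of normalization (`vector`, `minmax`) and FPR
#' direction (`cost`, `benefit`) on the same decision matrix and, when a
#' reference table of closeness scores is supplied, reports the largest
#' absolute deviation and whether the induced ordering matches. This is
#' the diagnostic used to probe which (if any) variant a published ranking
#' corresponds to.
#'
#' @param reports As in [build_decision_matrix()].
#' @param reference Optional tibble with `model_id` and `closeness` to
#'   compare against (e.g. [published_topsis_ranking()]).
#' @return A 4-row tibble: `normalization`, `fpr_direction`, a `scores`
#'   list-column, and (with a reference) `max_abs_dev` and `same_order`.
#' @export
topsis_variant_sweep <- function(reports, reference = NULL) {
  grid <- tidyr::expand_grid(normalization = c("vector", "minmax"),
                             fpr_direction = c("cost", "benefit"))
  grid$scores <- pmap(grid, function(normalization, fpr_direction) {
    crit <- topsis_criteria()
    crit$direction[crit$name == "fpr"] <- fpr_direction
    topsis_scores(build_decision_matrix(reports, crit),
                  normalization = normalization)
  })
  if (!is.null(reference)) {
    cmp <- map(grid$scores, function(sc) {
      j <- left_join(sc, rename(as_tibble(reference),
                                ref_closeness = "closeness"),
                     by = "model_id")
      tibble(max_abs_dev = max(abs(j$closeness - j$ref_closeness)),
             same_order = identical(
               arrange(j, desc(.data$closeness))$model_id,
               arrange(j, desc(.data$ref_closeness))$model_id))
    }) |> list_rbind()
    grid <- bind_cols(grid, cmp)
  }
  grid
}

#' Published eleven-model metric table
#'
#' The reference comparison table of the benchmarked study: the eight
#' evaluation metrics (percent) for all eleven models, as printed. Shipped
#' with the package so the ranking stage can be exercised on the exact
#' published inputs.
#'
#' @return An 11-row tibble: `model_id` plus the eight metric columns.
#' @export
published_model_metrics <- function() {
  readr::read_csv(system.file("extdata", "published_model_metrics.csv",
                              package = "crisprcleavr"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Published TOPSIS ranking
#'
#' The published closeness scores and ranks of the eleven models, used as
#' the reference for [topsis_variant_sweep()]. Note this ranking is not
#' reproduced by any standard TOPSIS variant applied to
#' [published_model_metrics()]; see the methods vignette.
#'
#' @return An 11-row tibble: `model_id`, `closeness`, `rank`.
#' @export
published_topsis_ranking <- function() {
  readr::read_csv(system.file("extdata", "published_topsis_ranking.csv",
                              package = "crisprcleavr"),
                  show_col_types = FALSE, progress = FALSE)
}
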