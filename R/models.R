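#' Enumerate the eleven classifier configurations
#'
#' The closed model suite benchmarked by the pipeline: six multilayer
#' perceptrons (two architectures, 25-25-25 and 30-20-10-5 hidden units,
#' each under logistic, tanh and ReLU activations, trained with Adam at
#' initial learning rate 0.001), four support vector machines (linear,
#' degree-3 polynomial, Gaussian RBF and sigmoid kernels), and one random
#' forest (100 trees, Gini split criterion, bootstrap sampling). The
#' pipeline refuses model ids outside this enumeration.
#'
#' @return An 11-row tibble: `model_id`, `label` (the compact name used in
#'   report tables), `family` (`ANN`/`SVM`/`RF`) and a `params` list-column
#'   of hyperparameters.
#' @export
model_configs <- function() {
  ann <- function(id, label, hidden, act) {
    tibble(model_id = id, label = label, family = "ANN",
           params = list(list(hidden = hidden, activation = act,
                              solver = "adam", learning_rate_init = 0.001,
                              max_epochs = 1000L, tol = 1e-4,
                              val_fraction = 0.1)))
  }
  svm <- function(id, label, kernel, degree = NULL) {
    tibble(model_id = id, label = label, family = "SVM",
           params = list(c(list(kernel = kernel, cost = 1),
                           if (!is.null(degree)) list(degree = degree))))
  }
  bind_rows(
    ann("ANN1-Logistic", "ANN1_logistic", c(25L, 25L, 25L), "logistic"),
    ann("ANN2-Logistic", "ANN2_logistic", c(30L, 20L, 10L, 5L), "logistic"),
    ann("ANN1-Tanh", "ANN1_tanh", c(25L, 25L, 25L), "tanh"),
    ann("ANN2-Tanh", "ANN2_tanh", c(30L, 20L, 10L, 5L), "tanh"),
    ann("ANN1-ReLU", "ANN1_ReLu", c(25L, 25L, 25L), "relu"),
    ann("ANN2-ReLU", "ANN2_ReLu", c(30L, 20L, 10L, 5L), "relu"),
    svm("SVM-Linear", "SVM_linear", "linear"),
    svm("SVM-Polynomial", "SVM_polynomial", "polynomial", degree = 3L),
    svm("SVM-Gaussian", "SVM_rbf", "radial"),
    svm("SVM-Sigmoid", "SVM_sigmoid", "sigmoid"),
    tibble(model_id = "RF", label = "Random_forest", family = "RF",
           params = list(list(ntree = 100L, criterion = "gini",
                              bootstrap = TRUE)))
  )
}

# resolve a model_id (or label) to its config row; closed enumeration
.resolve_config <- function(model) {
  cfg <- model_configs()
  hit <- cfg[cfg$model_id == model | cfg$label == model, ]
  if (nrow(hit) != 1L) {
    abort(paste0("unknown model id '", model, "'; valid ids: ",
                 paste(cfg$model_id, collapse = ", ")))
  }
  hit
}

# separate a featurized tibble into x matrix and y vector
.design <- function(data) {
  if (!"label" %in% names(data)) abort("data must contain a label column")
  feat_cols <- setdiff(names(data), c("site_id", "label", "split"))
  if (nrow(data) == 0L) abort("empty training set")
  x <- as.matrix(data[, feat_cols, drop = FALSE])
  if (!is.numeric(x)) abort("feature columns must all be numeric")
  list(x = x, y = as.integer(data$label), cols = feat_cols)
}

# zero-mean/unit-variance scaler fitted on the training design only;
# zero-variance columns pass through unscaled
.fit_scaler <- function(x) {
  mu <- colMeans(x)
  sig <- apply(x, 2L, sd)
  sig[!is.finite(sig) | sig == 0] <- 1
  list(center = mu, scale = sig)
}

.apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

#' Train one classifier on a featurized dataset
#'
#' Fits one of the eleven enumerated configurations on the feature matrix.
#' For the perceptron and SVM families, features are standardized to zero
#' mean and unit variance with statistics computed on the training data
#' only (the statistics travel with the fitted model); the random forest
#' uses raw features. Training is deterministic under `seed`.
#'
#' @param data A featurized tibble (as from [featurize_dataset()]): a
#'   `label` column plus numeric feature columns (`site_id`/`split`
#'   ignored).
#' @param model A model id or table label from [model_configs()].
#' @param seed Integer seed.
#' @return An object of class `cleavage_model`.
#' @export
train_model <- function(data, model, seed = 1L) {
  config <- .resolve_config(model)
  d <- .design(data)
  if (nrow(d$x) == 0L) abort("empty training set")
  if (length(unique(d$y)) < 2L) {
    abort("training set must contain both classes")
  }
  .with_seed(seed, {
    scaler <- NULL
    xs <- d$x
    if (config$family %in% c("ANN", "SVM")) {
      scaler <- .fit_scaler(d$x)
      xs <- .apply_scaler(d$x, scaler)
    }
    p <- config$params[[1L]]
    fit <- switch(
      config$family,
      ANN = mlp_fit(xs, d$y, hidden = p$hidden, activation = p$activation,
                    lr = p$learning_rate_init, max_epochs = p$max_epochs,
                    tol = p$tol, val_fraction = p$val_fraction),
      SVM = e1071::svm(xs, factor(d$y, levels = c(0L, 1L)),
                       kernel = p$kernel,
                       degree = p$degree %||% 3L,
                       cost = p$cost, probability = TRUE, scale = FALSE),
      RF = randomForest::randomForest(xs, factor(d$y, levels = c(0L, 1L)),
                                      ntree = p$ntree)
    )
    structure(list(config = config, scaler = scaler, fit = fit,
                   feature_names = d$cols, seed = seed,
                   n_train = nrow(d$x)),
              class = "cleavage_model")
  })
}

#' @export
print.cleavage_model <- function(x, ...) {
  cat(sprintf("<cleavage_model> %s (%s), %d features, n_train = %d\n",
              x$config$model_id, x$config$family,
              length(x$feature_names), x$n_train))
  invisible(x)
}

#' Predict cleavage scores for new sites
#'
#' One score in \[0, 1\] per row, interpretable as the probability the site
#' is a true (on-target) cleavage site. Thresholding is deferred to the
#' evaluation stage. SVM scores are Platt-calibrated probabilities (a
#' monotone mapping of the decision values, so ranking metrics such as AUC
#' are unaffected by the calibration).
#'
#' @param model A `cleavage_model`.
#' @param data A featurized tibble with the same feature columns the model
#'   was trained on.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict_scores <- function(model, data) {
  stopifnot(inherits(model, "cleavage_model"))
  feat_cols <- setdiff(names(data), c("site_id", "label", "split"))
  if (!identical(feat_cols, model$feature_names)) {
    abort(paste0("feature columns do not match the training registry (",
                 length(feat_cols), " vs ", length(model$feature_names),
                 " columns)"))
  }
  x <- as.matrix(data[, feat_cols, drop = FALSE])
  if (nrow(x) == 0L) abort("no rows to score")
  if (!is.null(model$scaler)) x <- .apply_scaler(x, model$scaler)
  fam <- model$config$family
  if (fam == "ANN") {
    return(unname(mlp_predict(model$fit, x)))
  }
  if (fam == "SVM") {
    pr <- predict(model$fit, x, probability = TRUE)
    return(unname(attr(pr, "probabilities")[, "1"]))
  }
  unname(predict(model$fit, x, type = "prob")[, "1"])
}

#' @export
predict.cleavage_model <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}

#' k-fold cross-validation of one configuration
#'
#' Splits the rows into `k` folds ([make_cv_folds()]), fits the
#' configuration on each training portion (including per-fold
#' standardization, so no statistic ever sees the held-out fold) and scores
#' the held-out fold. Fold assignment and each fit are deterministic under
#' `seed`.
#'
#' @param data A featurized tibble including `site_id` and `label`.
#' @param model A model id from [model_configs()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param threshold Score threshold for the per-fold confusion matrices.
#' @return A list with `folds` (a k-row tibble of per-fold eval reports)
#'   and `predictions` (a tibble `site_id`, `fold`, `label`, `score` of
#'   pooled out-of-fold predictions).
#' @export
cross_validate <- function(data, model, k = 5L, seed = 1L,
                           threshold = 0.5) {
  config <- .resolve_config(model)
  if (!"site_id" %in% names(data)) {
    data <- mutate(data, site_id = paste0("row", row_number()),
                   .before = 1L)
  }
  folds <- make_cv_folds(data$site_id, k = k, seed = seed)
  data <- left_join(data, folds, by = c(site_id = "id"))
  preds <- map(seq_len(k), function(f) {
    tr <- data[data$fold != f, ]
    va <- data[data$fold == f, ]
    m <- tryCatch(
      train_model(select(tr, -"fold"), config$model_id, seed = seed + f),
      error = function(e) abort(paste0("fold ", f, ": ",
                                       conditionMessage(e)))
    )
    tibble(site_id = va$site_id, fold = f, label = va$label,
           score = predict_scores(m, select(va, -"fold")))
  }) |> list_rbind()
  fold_reports <- map(seq_len(k), function(f) {
    p <- preds[preds$fold == f, ]
    rep <- metric_suite(p$label, p$score, threshold = threshold)
    mutate(rep, model_id = config$model_id, surface = "cv_fold",
           fold = f, n = nrow(p), .before = 1L)
  }) |> list_rbind()
  list(folds = fold_reports, predictions = preds)
}
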