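test_that("the model suite enumerates exactly eleven configurations", {
  cfg <- model_configs()
  expect_equal(nrow(cfg), 11L)
  expect_equal(sum(cfg$family == "ANN"), 6L)
  expect_equal(sum(cfg$family == "SVM"), 4L)
  expect_equal(sum(cfg$family == "RF"), 1L)
  expect_false(anyDuplicated(cfg$model_id) > 0)
  expect_false(anyDuplicated(cfg$label) > 0)
  # hyperparameters pinned to the benchmarked configurations
  ann1 <- cfg$params[[which(cfg$model_id == "ANN1-Logistic")]]
  expect_equal(ann1$hidden, c(25L, 25L, 25L))
  expect_equal(ann1$learning_rate_init, 0.001)
  ann2 <- cfg$params[[which(cfg$model_id == "ANN2-ReLU")]]
  expect_equal(ann2$hidden, c(30L, 20L, 10L, 5L))
  poly <- cfg$params[[which(cfg$model_id == "SVM-Polynomial")]]
  expect_equal(poly$degree, 3L)
  rf <- cfg$params[[which(cfg$model_id == "RF")]]
  expect_equal(rf$ntree, 100L)
  expect_error(train_model(shared_features(), "GBM"), "unknown model id")
})

test_that("random forest separates the synthetic classes on holdout", {
  f <- shared_features()
  tr <- dplyr::filter(f, split == "train") |> dplyr::select(-split)
  te <- dplyr::filter(f, split == "test") |> dplyr::select(-split)
  m <- train_model(tr, "RF", seed = 1L)
  rep <- evaluate_model(m, te)
  expect_gte(rep$auc, 90)
  expect_equal(rep$n, 114L)
})

test_that("training and prediction are deterministic under the seed", {
  f <- shared_features()
  tr <- dplyr::filter(f, split == "train") |> dplyr::select(-split)
  te <- dplyr::filter(f, split == "test") |> dplyr::select(-split)
  for (mid in c("RF", "SVM-Gaussian", "ANN2-Tanh")) {
    m1 <- train_model(tr, mid, seed = 5L)
    m2 <- train_model(tr, mid, seed = 5L)
    expect_identical(predict_scores(m1, te), predict_scores(m2, te),
                     label = mid)
  }
})

test_that("scores live in [0, 1] and rank on-targets above far off-targets", {
  f <- shared_features()
  tr <- dplyr::filter(f, split == "train") |> dplyr::select(-split)
  te <- dplyr::filter(f, split == "test") |> dplyr::select(-split)
  m <- train_model(tr, "RF", seed = 2L)
  sc <- predict_scores(m, te)
  expect_true(all(sc >= 0 & sc <= 1))
  on_scores <- sc[te$label == 1L]
  far <- sc[te$label == 0L & te$mismatches >= 4]
  expect_gt(median(on_scores), median(far))
  expect_error(predict_scores(m, te[, 1:10]), "registry")
  expect_error(predict_scores(m, te[0, ]), "no rows")
})

test_that("single-class training sets are refused", {
  f <- shared_features() |> dplyr::select(-split)
  expect_error(train_model(dplyr::filter(f, label == 1L), "RF"),
               "both classes")
  expect_error(train_model(f[0, ], "RF"), "empty")
})

test_that("permuted labels destroy the class signal", {
  # the no-signal level is estimated as the mean holdout AUC over several
  # independent label permutations, since a single 114-site draw is too
  # noisy to locate chance performance
  f <- shared_features()
  set.seed(77)
  aucs <- vapply(1:5, function(i) {
    perm <- f
    perm$label <- sample(perm$label)
    tr <- dplyr::filter(perm, split == "train") |> dplyr::select(-split)
    te <- dplyr::filter(perm, split == "test") |> dplyr::select(-split)
    m <- train_model(tr, "RF", seed = 3L + i)
    evaluate_model(m, te)$auc
  }, numeric(1))
  expect_gte(mean(aucs), 40)
  expect_lte(mean(aucs), 60)
})

test_that("cross-validation partitions 265 training records into 53-site folds", {
  f <- shared_features()
  tr <- dplyr::filter(f, split == "train") |> dplyr::select(-split)
  expect_equal(nrow(tr), 265L)
  cv <- cross_validate(tr, "RF", k = 5, seed = 4L)
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(cv$folds$n, rep(53L, 5))
  expect_setequal(cv$predictions$site_id, tr$site_id)
  # fold assignment deterministic under seed
  cv2 <- cross_validate(tr, "RF", k = 5, seed = 4L)
  expect_identical(cv$predictions$fold, cv2$predictions$fold)
  # CV estimate consistent with holdout performance
  te <- dplyr::filter(f, split == "test") |> dplyr::select(-split)
  hold <- evaluate_model(train_model(tr, "RF", seed = 4L), te)
  expect_lt(abs(mean(cv$folds$auc) - hold$auc), 10)
})

test_that("per-fold preprocessing does not leak validation information", {
  # noise features only; a cheat column is constant (zero) on every
  # training portion and equals the label on the held-out rows, so any
  # use of validation rows during fitting or scaling would inflate AUC
  set.seed(78)
  n <- 150
  x <- matrix(rnorm(n * 10), n)
  lab <- sample(0:1, n, replace = TRUE)
  data <- tibble::as_tibble(as.data.frame(x)) |>
    setNames(paste0("f", 1:10)) |>
    dplyr::mutate(site_id = paste0("r", 1:n), label = lab, .before = 1)
  folds <- make_cv_folds(data$site_id, k = 5, seed = 79L)
  data <- dplyr::left_join(data, folds, by = c(site_id = "id"))
  preds <- lapply(1:5, function(fd) {
    tr <- dplyr::filter(data, fold != fd) |> dplyr::select(-fold)
    va <- dplyr::filter(data, fold == fd) |> dplyr::select(-fold)
    tr$cheat <- 0
    va$cheat <- as.numeric(va$label)
    m <- train_model(tr, "SVM-Linear", seed = 80L)
    tibble::tibble(label = va$label, score = predict_scores(m, va))
  }) |> dplyr::bind_rows()
  cv_auc <- auc_score(preds$label, preds$score)
  expect_gte(cv_auc, 0.35)
  expect_lte(cv_auc, 0.65)
})

test_that("tidy and glance summarise fitted models", {
  f <- shared_features()
  tr <- dplyr::filter(f, split == "train") |> dplyr::select(-split)
  m <- train_model(tr, "RF", seed = 1L)
  td <- tidy(m)
  expect_true(all(c("term", "value") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$model_id, "RF")
  expect_equal(gl$n_train, 265L)
  expect_false(gl$standardized)
  gl_ann <- glance(train_model(tr, "ANN1-Logistic", seed = 1L))
  expect_true(gl_ann$standardized)
  expect_gte(gl_ann$epochs, 1L)
})
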