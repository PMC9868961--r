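#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown fields are
#' rejected. One global seed fans out to per-stage seeds by a fixed
#' documented derivation (`stage seed = seed * 100 + stage index`, stages
#' numbered data = 1, split = 2, models = 3), so each stage is
#' independently reproducible.
#'
#' @param profile A `generation_profile` for synthetic input, or `NULL`
#'   when reading from files.
#' @param guide_fasta,site_table Input paths, used when `profile` is
#'   `NULL`.
#' @param train_fraction Training proportion (default 0.7).
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param model_ids Models to run (default all eleven).
#' @param threshold Score threshold for confusion matrices (default 0.5).
#' @param topsis_normalization `"vector"` or `"minmax"`.
#' @param seed Global integer seed.
#' @param out_dir Output directory for the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(profile = default_profile(),
                            guide_fasta = NULL, site_table = NULL,
                            train_fraction = 0.7, cv_folds = 5L,
                            model_ids = model_configs()$model_id,
                            threshold = 0.5,
                            topsis_normalization = "vector",
                            seed = 1L, out_dir = tempfile("crisprcleavr_")) {
  if (is.null(profile) && (is.null(guide_fasta) || is.null(site_table))) {
    abort("either a generation profile or input paths must be given")
  }
  unknown <- setdiff(model_ids, model_configs()$model_id)
  if (length(unknown)) {
    abort(paste0("unknown model id(s): ", paste(unknown, collapse = ", ")))
  }
  if (cv_folds < 2L) abort("cv_folds must be at least 2")
  structure(list(profile = profile, guide_fasta = guide_fasta,
                 site_table = site_table,
                 train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), model_ids = model_ids,
                 threshold = threshold,
                 topsis_normalization = topsis_normalization,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] can be set in a YAML document;
#' generation-profile knobs go under a `profile:` mapping. Unknown keys are
#' rejected before any work is done.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("profile", "guide_fasta", "site_table", "train_fraction",
               "cv_folds", "model_ids", "threshold",
               "topsis_normalization", "seed", "out_dir")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    abort(paste0("unknown config key(s) in ", path, ": ",
                 paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$profile)) {
    prof_allowed <- c("context_length", "mismatch_probs",
                      "pam_proximal_bias", "bulge_probability",
                      "nag_pam_probability", "guide_length_probs")
    unknown_p <- setdiff(names(raw$profile), prof_allowed)
    if (length(unknown_p)) {
      abort(paste0("unknown profile key(s): ",
                   paste(unknown_p, collapse = ", ")))
    }
    raw$profile <- do.call(default_profile, raw$profile)
  }
  do.call(pipeline_config, raw)
}

# stage-seed derivation (documented in pipeline_config)
.stage_seed <- function(seed, stage) seed * 100L + stage

#' Run the whole benchmarking study
#'
#' Orchestrates every stage end to end: obtain the labeled dataset
#' (synthetic generation under the profile, or reading the input files),
#' featurize it, split 70/30, train each configured model on the training
#' portion, evaluate it on the holdout and under k-fold cross-validation,
#' assemble the model-by-metric comparison table, and rank the models with
#' TOPSIS. All artifacts are written into the run directory: the dataset
#' (guide FASTA + site CSV), the feature matrix, fitted models, per-model
#' reports for every surface (`holdout`, `cv_mean`, `cv_pooled`), the
#' comparison and ranking CSVs, and a manifest capturing every seed and
#' knob needed for bit-reproduction.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `out_dir`, the `dataset`, `features`,
#'   fitted `models`, the per-surface `reports`, the Table-shaped
#'   `metrics` tibble (holdout surface) and the TOPSIS `ranking`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  # stage 1: data
  if (!is.null(config$profile)) {
    say("stage data: generating synthetic dataset")
    ds <- generate_dataset(config$profile, seed = .stage_seed(config$seed,
                                                              1L))
  } else {
    say("stage data: reading %s", config$site_table)
    ds <- read_dataset(config$guide_fasta, config$site_table)
  }
  write_dataset(ds, file.path(config$out_dir, "guides.fasta"),
                file.path(config$out_dir, "sites.csv"))

  # stage 2: features + split
  say("stage featurize: %d sites", nrow(ds$sites))
  features <- featurize_dataset(ds)
  ds <- split_dataset(ds, train_fraction = config$train_fraction,
                      seed = .stage_seed(config$seed, 2L))
  features$split <- ds$sites$split[match(features$site_id,
                                         ds$sites$site_id)]
  write_feature_matrix(select(features, -"split"),
                       file.path(config$out_dir, "feature_matrix.csv"))
  train <- filter(features, .data$split == "train") |> select(-"split")
  test <- filter(features, .data$split == "test") |> select(-"split")

  # stage 3: models + evaluation
  model_dir <- file.path(config$out_dir, "models")
  dir.create(model_dir, showWarnings = FALSE)
  models <- list()
  reports <- list()
  for (mi in seq_along(config$model_ids)) {
    mid <- config$model_ids[mi]
    seed_m <- .stage_seed(config$seed, 3L) + mi
    say("stage train: %s", mid)
    fit <- train_model(train, mid, seed = seed_m)
    models[[mid]] <- fit
    saveRDS(fit, file.path(model_dir, paste0(gsub("[^A-Za-z0-9]", "_",
                                                  mid), ".rds")))
    hold <- evaluate_model(fit, test, threshold = config$threshold)
    cv <- cross_validate(train, mid, k = config$cv_folds, seed = seed_m,
                         threshold = config$threshold)
    pooled <- metric_suite(cv$predictions$label, cv$predictions$score,
                           threshold = config$threshold) |>
      mutate(model_id = mid, surface = "cv_pooled",
             n = nrow(cv$predictions), .before = 1L)
    reports[[mid]] <- bind_rows(
      select(hold, -"counts", -"roc"),
      cv_mean_report(cv$folds),
      select(pooled, -"counts", -"roc"))
  }
  reports <- list_rbind(reports)
  reports$label <- model_configs()$label[match(reports$model_id,
                                               model_configs()$model_id)]
  readr::write_csv(reports, file.path(config$out_dir,
                                      "reports_all_surfaces.csv"),
                   progress = FALSE)
  metrics <- filter(reports, .data$surface == "holdout") |>
    select("label", "accuracy":"auc") |>
    rename(model_id = "label")
  readr::write_csv(metrics, file.path(config$out_dir,
                                      "model_metrics.csv"),
                   progress = FALSE)

  # stage 4: TOPSIS ranking
  crit <- topsis_criteria()
  vals <- as.matrix(metrics[, crit$name])
  # a criterion on which every model agrees cannot discriminate and would
  # make the column normalization degenerate; drop it from the ranking
  keep <- apply(vals, 2L, function(x) max(x) - min(x) > 0 && any(x != 0))
  if (any(!keep)) {
    say("stage rank: dropping non-discriminating criteria: %s",
        paste(crit$name[!keep], collapse = ", "))
    crit <- crit[keep, ]
  }
  if (nrow(metrics) >= 2L && nrow(crit) >= 1L) {
    say("stage rank: TOPSIS over %d models", nrow(metrics))
    ranking <- topsis_scores(build_decision_matrix(metrics, crit),
                             normalization = config$topsis_normalization)
  } else {
    say("stage rank: single model, closeness undefined")
    ranking <- tibble(model_id = metrics$model_id, closeness = NA_real_,
                      rank = 1L)
  }
  readr::write_csv(ranking, file.path(config$out_dir,
                                      "topsis_ranking.csv"),
                   progress = FALSE)

  manifest <- list(
    package = "crisprcleavr",
    version = as.character(utils::packageVersion("crisprcleavr")),
    seed = config$seed,
    stage_seeds = list(data = .stage_seed(config$seed, 1L),
                       split = .stage_seed(config$seed, 2L),
                       models = .stage_seed(config$seed, 3L)),
    train_fraction = config$train_fraction,
    cv_folds = config$cv_folds,
    threshold = config$threshold,
    topsis_normalization = config$topsis_normalization,
    model_ids = config$model_ids,
    synthetic = !is.null(config$profile),
    profile = if (!is.null(config$profile)) {
      p <- unclass(config$profile)
      p$crops <- as.data.frame(p$crops)
      p
    }
  )
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = config$out_dir, dataset = ds,
                 features = features, models = models, reports = reports,
                 metrics = metrics, ranking = ranking))
}
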