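#' One-command synthetic end-to-end demonstration
#'
#' Generates a synthetic phantom cohort, trains the reduced network, fits the
#' SVR head, evaluates held-out regression quality, then builds a second
#' CN/AD cohort, computes brain-age gaps with the trained pipeline and runs
#' the four-classifier majority-vote AD detection.  All stage seeds are
#' derived from the single `seed` by fixed offsets, so two runs with the same
#' seed produce identical metric files.
#'
#' At `scale = "test"` the run uses a 16 x 16 x 8 grid, 48 regression
#' subjects and a short training schedule so it completes in seconds on one CPU;
#' `scale = "full"` uses the full 64 x 64 x 32 architecture and is intended
#' for long unattended runs.
#'
#' @param seed integer master seed.
#' @param scale `"test"` or `"full"`.
#' @param out_dir output directory for metric files (created if needed).
#' @param verbose print progress.
#' @return Invisibly, a list with `metrics` (regression), `svr_metrics`,
#'   `ad` (classification reports) and the written file paths.
#' @export
run_demo <- function(seed = 1L, scale = c("test", "full"),
                     out_dir = tempfile("brainage_demo_"), verbose = FALSE) {
  scale <- match.arg(scale)
  seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (scale == "test") {
    params <- phantom_params(shape = c(16, 16, 8), noise_sd = 0.01)
    cfg <- network_config(features = c(4, 8, 16), types = c("res", "att", "res"),
                          input_shape = c(16, 16, 8), dense_units = 32L)
    n_reg <- 48L
    n_ad <- 40L
    epochs <- 40L
  } else {
    params <- phantom_params(shape = c(64, 64, 32), noise_sd = 0.01)
    cfg <- network_config()
    n_reg <- 240L
    n_ad <- 80L
    epochs <- 100L
  }
  effective <- list(seed = seed, scale = scale,
                    shape = params$shape, n_regression_subjects = n_reg,
                    n_ad_cohort_subjects = n_ad, epochs = epochs,
                    features = cfg$features, types = cfg$types,
                    dense_units = cfg$dense_units)
  jsonlite::write_json(effective, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (verbose) message("generating cohort of ", n_reg, " subjects ...")
  gen <- make_cohort(n_reg, age_range = c(20, 80), ad_fraction = 0,
                     params = params, seed = seed)
  ch <- split_subjects(gen$cohort, test_fraction = 0.25, val_fraction = 0.10,
                       seed = seed + 1L)
  vols <- lapply(gen$volumes, function(v)
    normalize_intensity(extract_brain(v, mask = v$mask)))
  sets <- lapply(c("train", "val", "test"), function(part) {
    idx <- which(ch$records$split == part)
    brainage_dataset(vols[idx], ch$records$age[idx], ch$records$sex[idx],
                     ch$records$diagnosis[idx])
  })
  names(sets) <- c("train", "val", "test")

  if (verbose) message("training for ", epochs, " epochs ...")
  model <- build_network(cfg, seed = seed + 2L)
  model <- train_network(model, sets$train, sets$val,
                         train_spec(epochs = epochs, seed = seed + 3L),
                         verbose = verbose)
  metrics <- evaluate_model(model, sets$test)
  baseline_mae <- mean(abs(sets$test$age - mean(sets$train$age)))

  feats_train <- extract_features(model, sets$train)
  head_svr <- fit_svr(feats_train)
  feats_test <- extract_features(model, sets$test)
  svr_pred <- predict_svr(head_svr, feats_test)
  svr_metrics <- regression_metrics(sets$test$age, svr_pred)

  if (verbose) message("AD cohort + classification ...")
  gen_ad <- make_cohort(n_ad, age_range = c(55, 80), ad_fraction = 0.5,
                        params = params, seed = seed + 4L)
  vols_ad <- lapply(gen_ad$volumes, function(v)
    normalize_intensity(extract_brain(v, mask = v$mask)))
  r_ad <- gen_ad$cohort$records
  ds_ad <- brainage_dataset(vols_ad, r_ad$age, r_ad$sex, r_ad$diagnosis)
  pred_ad <- predict_svr(head_svr, extract_features(model, ds_ad))
  bag <- compute_bag(ds_ad$age, pred_ad)
  ad <- detect_ad(bag, ds_ad$diagnosis, test_fraction = 0.15, seed = seed + 5L)

  reg_out <- list(
    n_test = metrics$n,
    baseline_mae = baseline_mae,
    network = metrics[c("mae", "rmse", "pcc", "srcc", "r2")],
    svr_head = svr_metrics[c("mae", "rmse", "pcc", "srcc", "r2")])
  cls_out <- list(
    n_test = ad$ensemble$n,
    ensemble = ad$ensemble[c("confusion", "precision", "recall", "f1",
                             "accuracy", "auc")],
    per_classifier = lapply(ad$per_classifier, function(r)
      r[c("precision", "recall", "f1", "accuracy", "auc")]),
    mean_bag_cn = mean(bag[ds_ad$diagnosis == "CN"]),
    mean_bag_ad = mean(bag[ds_ad$diagnosis == "AD"]))
  paths <- list(
    regression = file.path(out_dir, "regression_metrics.json"),
    classification = file.path(out_dir, "classifier_report.json"),
    model = file.path(out_dir, "model.rds"))
  jsonlite::write_json(reg_out, paths$regression, auto_unbox = TRUE,
                       pretty = TRUE, digits = 10)
  jsonlite::write_json(cls_out, paths$classification, auto_unbox = TRUE,
                       pretty = TRUE, digits = 10)
  save_model(model, paths$model)
  invisible(list(metrics = metrics, svr_metrics = svr_metrics, ad = ad,
                 baseline_mae = baseline_mae, model = model, paths = paths))
}
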