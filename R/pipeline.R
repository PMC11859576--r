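#' End-to-end imbalanced-learning pipeline
#'
#' Runs the full method on one dataset: stratified train/test split,
#' min-max normalization (fit on the training portion, applied to both),
#' AMOM-DUMS hybrid resampling of the training data, F-score wrapper
#' feature selection, GA search for the best stacked classifier subset,
#' final stack fit, and evaluation on the untouched test split. All
#' stage seeds derive deterministically from `seed`.
#'
#' @param dataset an [imb_dataset]; alternatively give `preset`.
#' @param preset a [scenario_preset()] name to simulate when `dataset`
#'   is NULL.
#' @param seed integer master seed.
#' @param test_fraction held-out fraction per class (default 0.3).
#' @param m,target_ratio resampling parameters, see [amom_dums()].
#' @param wrapper_classifier classifier for [wrapper_select()] (default
#'   `"logit"` for speed; `"adaboost"` mirrors the boosting wrapper).
#' @param max_dim largest feature-subset size tried (default all).
#' @param pool first-layer [classifier_pool()]; default
#'   `default_pool("fast")`.
#' @param ga an [ga_config()] (its `rng_seed` is overridden by the
#'   derived stage seed).
#' @param cv_folds stratified folds used by the wrapper, the stack and
#'   the GA fitness (default 3).
#' @param baseline also train a single RBF-SVM on the normalized,
#'   unsampled, unselected training data as the comparison model
#'   (default TRUE).
#' @param threshold decision threshold for threshold-bound metrics
#'   (default 0.5).
#' @return object of class `imb_pipeline_result`: list with
#'   `report` (test-set [classification_report()] of the stack),
#'   `baseline_report` (idem for the single SVM, or NULL),
#'   `ur_before`, `ur_after_sampling`, `sampling` (masks/iterations),
#'   `wrapper` (feature-selection result), `ga` (search result),
#'   `stack` (the fitted `imb_stack_model`), `selected_features`,
#'   `test_indices`, `seed`.
#' @examples
#' \donttest{
#' res <- run_pipeline(preset = "tableA", seed = 1,
#'                     ga = ga_config(population_size = 8, generations = 3))
#' res$report
#' }
#' @export
run_pipeline <- function(dataset = NULL, preset = NULL, seed = 1L,
                         test_fraction = 0.3, m = 5L, target_ratio = 1.0,
                         wrapper_classifier = "logit", max_dim = NULL,
                         pool = default_pool("fast"), ga = ga_config(),
                         cv_folds = 3L, baseline = TRUE, threshold = 0.5) {
  if (is.null(dataset)) {
    if (is.null(preset)) stop("supply a dataset or a preset name",
                              call. = FALSE)
    dataset <- scenario_generate(
      scenario_preset(preset, rng_seed = derive_seed(seed, 11)))
  }
  check_both_classes(dataset, "the pipeline")
  ur_before <- compute_ur(dataset)

  # stratified train/test split
  test_idx <- with_seed(derive_seed(seed, 12), {
    unlist(lapply(c(0L, 1L), function(cls) {
      idx <- which(dataset$y == cls)
      sample(idx, max(1L, round(test_fraction * length(idx))))
    }))
  })
  tr_idx <- setdiff(seq_len(nrow(dataset$X)), test_idx)
  train <- imb_dataset(dataset$X[tr_idx, , drop = FALSE], dataset$y[tr_idx],
                       dataset$feature_names)
  test <- imb_dataset(dataset$X[test_idx, , drop = FALSE],
                      dataset$y[test_idx], dataset$feature_names)

  norm <- minmax_normalize(train)
  train <- norm$dataset
  test <- minmax_normalize(test, params = norm$params)$dataset

  resample <- list(m = m, target_ratio = target_ratio)
  sampling <- amom_dums(train, m = m, target_ratio = target_ratio,
                        seed = derive_seed(seed, 13))
  sampled <- sampling$dataset
  ur_after <- compute_ur(sampled)

  # every cross-validated quantity below oversamples *inside* the
  # training folds and evaluates on untouched real rows; the full-data
  # resample above is used only for deployment fits and reporting
  wrapper <- wrapper_select(train, classifier = wrapper_classifier,
                            max_dim = max_dim, cv_folds = cv_folds,
                            seed = derive_seed(seed, 14),
                            resample = resample)
  sel <- wrapper$selected_features
  sel_cols <- match(sel, sampled$feature_names)
  sampled_sel <- imb_dataset(sampled$X[, sel_cols, drop = FALSE],
                             sampled$y, sel)
  train_sel <- imb_dataset(train$X[, sel_cols, drop = FALSE], train$y, sel)

  oof <- pool_oof_matrix(train_sel, pool, cv_folds,
                         seed = derive_seed(seed, 15),
                         resample = resample)
  ga$rng_seed <- derive_seed(seed, 15)
  ga_res <- ga_optimize(train_sel, pool = pool, config = ga,
                        cv_folds = cv_folds, oof = oof)
  stack <- fit_stack(sampled_sel, ga_res$best_chromosome, pool = pool,
                     cv_folds = cv_folds, seed = derive_seed(seed, 16),
                     oof = ga_res$oof)

  p_test <- predict(stack, test$X[, sel_cols, drop = FALSE])
  report <- classification_report(test$y, p_test, threshold = threshold,
                                  positive_label = 0L)

  # two single-SVM comparators: (i) the un-pipelined baseline — an
  # RBF-SVM trained directly on the normalized, imbalanced training data
  # with all features, i.e. what a practitioner gets without this
  # toolchain; (ii) a diagnostic SVM given the pipeline's own resampled,
  # feature-selected training data, isolating the model-class contrast
  baseline_report <- NULL
  svm_pipeline_report <- NULL
  if (baseline) {
    spec <- if ("svm" %in% names(pool)) pool[["svm"]]
            else default_pool("fast")[["svm"]]
    fit_raw <- fit_classifier(spec, train$X, train$y,
                              seed = derive_seed(seed, 17))
    p_raw <- predict_minority_prob(fit_raw, test$X)
    baseline_report <- classification_report(test$y, p_raw,
                                             threshold = threshold,
                                             positive_label = 0L)
    fit_pp <- fit_classifier(spec, sampled_sel$X, sampled_sel$y,
                             seed = derive_seed(seed, 18))
    p_pp <- predict_minority_prob(fit_pp, test$X[, sel_cols, drop = FALSE])
    svm_pipeline_report <- classification_report(test$y, p_pp,
                                                 threshold = threshold,
                                                 positive_label = 0L)
  }

  structure(list(report = report,
                 baseline_report = baseline_report,
                 svm_pipeline_report = svm_pipeline_report,
                 ur_before = ur_before,
                 ur_after_sampling = ur_after,
                 sampling = sampling[c("deleted_indices", "iterations")],
                 wrapper = wrapper,
                 ga = ga_res[c("best_chromosome", "best_fitness",
                               "history", "evaluations")],
                 stack = stack,
                 selected_features = sel,
                 test_indices = test_idx,
                 seed = seed),
            class = "imb_pipeline_result")
}

#' @export
print.imb_pipeline_result <- function(x, ...) {
  cat("<imb_pipeline_result> seed", x$seed, "\n")
  cat(sprintf("  UR %.3f -> %.3f after resampling\n",
              x$ur_before, x$ur_after_sampling))
  cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  cat("  chromosome:", paste(x$ga$best_chromosome, collapse = ""), "\n")
  cat(sprintf("  test: recall %.3f  F %.3f  AUC %.3f\n",
              x$report$recall, x$report$f_score, x$report$auc))
  if (!is.null(x$baseline_report)) {
    cat(sprintf("  SVM baseline (raw data): recall %.3f  F %.3f  AUC %.3f\n",
                x$baseline_report$recall, x$baseline_report$f_score,
                x$baseline_report$auc))
    cat(sprintf("  SVM with pipeline preprocessing: recall %.3f  F %.3f  AUC %.3f\n",
                x$svm_pipeline_report$recall, x$svm_pipeline_report$f_score,
                x$svm_pipeline_report$auc))
  }
  invisible(x)
}

#' Serialize a pipeline result to JSON
#'
#' Writes the scalar summary of a pipeline run (URs, selected features,
#' chromosome, fitness history, test metrics and baseline metrics) to a
#' machine-readable report.
#'
#' @param result an `imb_pipeline_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(result, path) {
  stopifnot(inherits(result, "imb_pipeline_result"))
  metrics <- function(r) {
    if (is.null(r)) return(NULL)
    r[c("accuracy", "precision", "recall", "recall_other", "f_score",
        "auc")]
  }
  out <- list(seed = result$seed,
              ur_before = result$ur_before,
              ur_after_sampling = result$ur_after_sampling,
              deleted_rows = length(result$sampling$deleted_indices),
              cleaning_iterations = result$sampling$iterations,
              best_dimension = result$wrapper$best_dimension,
              selected_features = result$selected_features,
              baseline_auc_no_fs = result$wrapper$baseline_auc_no_fs,
              chromosome = paste(result$ga$best_chromosome, collapse = ""),
              ga_best_fitness = result$ga$best_fitness,
              ga_history = result$ga$history,
              test_metrics = metrics(result$report),
              svm_baseline_metrics = metrics(result$baseline_report),
              svm_pipeline_metrics = metrics(result$svm_pipeline_report))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
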