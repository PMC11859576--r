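#' Standard F-score of a feature
#'
#' Fisher-style discriminability of a single feature for a binary
#' outcome: squared deviations of both class means from the overall mean,
#' divided by the sum of the two within-class sample variances. Here the
#' positive class (`n+`) is the majority label 1 and the negative class
#' (`n-`) the minority label 0, matching the encoding used throughout the
#' package. Larger is more discriminative.
#'
#' When both within-class variances are zero the ratio is degenerate:
#' the function returns `Inf` with a warning if the class means differ
#' (perfect separator), and 0 if the feature is globally constant.
#'
#' @param dataset an [imb_dataset] with at least 2 samples per class.
#' @param feature_index column index (or name) of the feature.
#' @return non-negative numeric (possibly `Inf`).
#' @export
fscore_standard <- function(dataset, feature_index) {
  fscore_terms(dataset, feature_index, improved = FALSE)
}

#' Improved F-score of a feature
#'
#' Identical numerator to [fscore_standard()], but the denominator keeps
#' only the positive-class (majority, label 1) variance term. Dropping
#' the minority-class variance stops an imbalanced feature's score being
#' dominated by a handful of rare-class samples; a larger value marks a
#' stronger ability to recognize the small class. Never smaller than the
#' standard score when the dropped variance term is positive.
#'
#' @inheritParams fscore_standard
#' @return non-negative numeric (possibly `Inf`).
#' @export
fscore_improved <- function(dataset, feature_index) {
  fscore_terms(dataset, feature_index, improved = TRUE)
}

fscore_terms <- function(dataset, feature_index, improved) {
  stopifnot(inherits(dataset, "imb_dataset"))
  v <- dataset$X[, feature_index]
  pos <- dataset$y == 1L   # n+ : majority
  neg <- dataset$y == 0L   # n- : minority
  if (sum(pos) < 2L || sum(neg) < 2L) {
    stop("F-scores need >= 2 samples in each class (have ",
         sum(neg), " minority, ", sum(pos), " majority)", call. = FALSE)
  }
  mu <- mean(v); mu_p <- mean(v[pos]); mu_n <- mean(v[neg])
  num <- (mu_p - mu)^2 + (mu_n - mu)^2
  den <- stats::var(v[pos])
  if (!improved) den <- den + stats::var(v[neg])
  if (den == 0) {
    if (num == 0) return(0)
    warning("zero within-class variance with separated means: ",
            "degenerate F-score flagged as Inf", call. = FALSE)
    return(Inf)
  }
  num / den
}

#' Rank features by F-score
#'
#' Computes standard and improved F-scores for every feature and ranks by
#' the chosen variant, descending. `Inf` (degenerate perfect separators)
#' sorts above all finite scores; ties are broken by original column
#' order.
#'
#' @param dataset an [imb_dataset].
#' @param variant `"improved"` (default) or `"standard"` — which score
#'   drives the ranking.
#' @return data frame of class `imb_feature_scores` with columns
#'   `feature_name`, `f_standard`, `f_improved`, `rank`, sorted by rank.
#' @export
rank_features <- function(dataset, variant = c("improved", "standard")) {
  variant <- match.arg(variant)
  p <- ncol(dataset$X)
  fs <- vapply(seq_len(p), function(j) fscore_standard(dataset, j), numeric(1))
  fi <- vapply(seq_len(p), function(j) fscore_improved(dataset, j), numeric(1))
  key <- if (variant == "improved") fi else fs
  ord <- order(-key, seq_len(p))  # ties -> original column order
  rank <- integer(p); rank[ord] <- seq_len(p)
  out <- data.frame(feature_name = dataset$feature_names,
                    f_standard = fs, f_improved = fi, rank = rank,
                    stringsAsFactors = FALSE)
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("imb_feature_scores", "data.frame")
  out
}

#' Pick the feature-subset size by wrapped cross-validation
#'
#' The filter-plus-wrapper loop: features are ranked by F-score, then for
#' each candidate dimension `k = 1..max_dim` a classifier is trained on
#' the top-`k` features under stratified cross-validation and scored by
#' mean AUC; the dimension with the highest mean AUC wins (ties go to the
#' smallest `k`, i.e. parsimony). The all-features AUC is recorded as the
#' no-selection baseline. With the default `leaky_single_pass = FALSE`
#' the ranking is recomputed inside each training fold so the held-out
#' fold never informs the selection; `TRUE` ranks once on the full data,
#' the simpler flow at a small risk of optimistic bias.
#'
#' @param dataset an [imb_dataset].
#' @param classifier a [classifier_spec()] or the id of a
#'   [default_pool()] member; default `"adaboost"`.
#' @param max_dim largest subset size to try (default all features).
#' @param cv_folds stratified folds (default 5).
#' @param variant F-score variant driving the ranking.
#' @param seed integer seed for fold assignment and any learner RNG.
#' @param leaky_single_pass rank once on all rows instead of per fold.
#' @param groups optional fold-grouping vector (see [stratified_folds()]);
#'   pass [sampling_groups()] output when the data were oversampled.
#' @param eval_mask optional logical row mask: held-out AUCs are computed
#'   on these rows only, so oversampled pipelines can exclude synthetic
#'   points from evaluation.
#' @param resample optional list with `m`, `target_ratio` (and
#'   optionally `policy`): apply [amom_dums()] inside each training fold
#'   (and to the full data for the final ranking), treating `dataset`
#'   itself as unsampled. Held-out evaluation rows stay untouched — the
#'   leak-free way to combine oversampling with the wrapper.
#' @return object of class `imb_wrapper_result`: list with
#'   `auc_by_dimension` (named numeric, names = k), `best_dimension`,
#'   `selected_features` (character, length `best_dimension`, from the
#'   full-data ranking), `baseline_auc_no_fs`, `scores` (the full-data
#'   [rank_features()] table).
#' @export
wrapper_select <- function(dataset, classifier = "adaboost", max_dim = NULL,
                           cv_folds = 5L, variant = c("improved", "standard"),
                           seed = NULL, leaky_single_pass = FALSE,
                           groups = NULL, eval_mask = NULL,
                           resample = NULL) {
  variant <- match.arg(variant)
  spec <- resolve_classifier(classifier)
  p <- ncol(dataset$X)
  if (is.null(max_dim)) max_dim <- p
  if (max_dim > p) stop("max_dim (", max_dim, ") exceeds feature count (",
                        p, ")", call. = FALSE)
  folds <- stratified_folds(dataset$y, cv_folds, seed = derive_seed(seed, 1),
                            groups = groups)
  if (is.null(eval_mask)) eval_mask <- rep(TRUE, nrow(dataset$X))

  # per-fold training data; oversampled inside the fold when requested,
  # so held-out rows (always real) never meet their own interpolants
  fold_train <- lapply(seq_len(cv_folds), function(f) {
    tr_ds <- imb_dataset(dataset$X[folds != f, , drop = FALSE],
                         dataset$y[folds != f], dataset$feature_names)
    if (is.null(resample)) return(tr_ds)
    amom_dums(tr_ds, m = resample$m %||% 5L,
              target_ratio = resample$target_ratio %||% 1.0,
              seed = derive_seed(seed, 400L + f),
              policy = resample$policy %||% "majority")$dataset
  })
  ranking_data <- if (is.null(resample)) {
    dataset
  } else {
    amom_dums(dataset, m = resample$m %||% 5L,
              target_ratio = resample$target_ratio %||% 1.0,
              seed = derive_seed(seed, 499L),
              policy = resample$policy %||% "majority")$dataset
  }
  full_scores <- rank_features(ranking_data, variant)
  full_order <- match(full_scores$feature_name, dataset$feature_names)

  fold_auc <- function(cols) {
    vapply(seq_len(cv_folds), function(f) {
      te <- folds == f & eval_mask
      tr_ds <- fold_train[[f]]
      fit <- fit_classifier(spec, tr_ds$X[, cols, drop = FALSE], tr_ds$y,
                            seed = derive_seed(seed, 100 + f))
      p_te <- predict_minority_prob(fit, dataset$X[te, cols, drop = FALSE])
      auc(dataset$y[te], p_te, positive_label = 0L)
    }, numeric(1))
  }

  auc_by_dim <- numeric(max_dim)
  if (leaky_single_pass) {
    for (k in seq_len(max_dim)) {
      auc_by_dim[k] <- mean(fold_auc(full_order[seq_len(k)]))
    }
  } else {
    # rank inside each training fold, evaluate on the held-out fold
    per_fold <- matrix(NA_real_, cv_folds, max_dim)
    for (f in seq_len(cv_folds)) {
      tr_ds <- fold_train[[f]]
      ord_f <- match(rank_features(tr_ds, variant)$feature_name,
                     dataset$feature_names)
      te <- folds == f & eval_mask
      for (k in seq_len(max_dim)) {
        cols <- ord_f[seq_len(k)]
        fit <- fit_classifier(spec, tr_ds$X[, cols, drop = FALSE], tr_ds$y,
                              seed = derive_seed(seed, 100 + f))
        p_te <- predict_minority_prob(fit, dataset$X[te, cols, drop = FALSE])
        per_fold[f, k] <- auc(dataset$y[te], p_te, positive_label = 0L)
      }
    }
    auc_by_dim <- colMeans(per_fold)
  }
  baseline <- mean(fold_auc(seq_len(p)))
  best_k <- which.max(auc_by_dim)  # which.max takes the first (smallest k)
  names(auc_by_dim) <- seq_len(max_dim)
  structure(list(auc_by_dimension = auc_by_dim,
                 best_dimension = as.integer(best_k),
                 selected_features =
                   full_scores$feature_name[seq_len(best_k)],
                 baseline_auc_no_fs = baseline,
                 scores = full_scores),
            class = "imb_wrapper_result")
}

#' @export
print.imb_wrapper_result <- function(x, ...) {
  cat("<imb_wrapper_result> best dimension:", x$best_dimension,
      sprintf("(AUC %.3f; all-feature baseline %.3f)\n",
              x$auc_by_dimension[x$best_dimension], x$baseline_auc_no_fs))
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

resolve_classifier <- function(classifier) {
  if (inherits(classifier, "imb_classifier_spec")) return(classifier)
  pool <- default_pool("fast")
  if (is.character(classifier) && classifier %in% names(pool)) {
    return(pool[[classifier]])
  }
  stop("unknown classifier '", classifier, "'; supply a classifier_spec or ",
       "one of: ", paste(names(pool), collapse = ", "), call. = FALSE)
}
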