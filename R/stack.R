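## Two-layer stacked generalization. First layer: a subset of the
## 10-classifier pool selected by a chromosome bitstring. Second layer: a
## ridge-regularized logistic meta-learner trained on out-of-fold
## first-layer probabilities, P(v = 1 | u) = 1 / (1 + exp(-w'u)).

# Ridge logistic meta-learner as a plain (intercept, weights) pair.
# Classes are reweighted to balance (so the 0.5 threshold stays
# meaningful on imbalanced data) and the ridge penalty is chosen by an
# internal deterministic cross-validation over the glmnet path. glmnet
# needs >= 2 predictors; a single column falls back to weighted glm,
# which needs no shrinkage in one dimension.
meta_fit <- function(Z, y, lambda = NULL) {
  y_min <- as.numeric(y == 0L)
  n0 <- sum(y_min); n1 <- length(y_min) - n0
  w <- ifelse(y_min == 1, length(y_min) / (2 * n0),
              length(y_min) / (2 * n1))
  if (ncol(Z) >= 2L) {
    if (is.null(lambda)) {
      foldid <- ((seq_along(y_min) * 7L) %% 3L) + 1L
      cvfit <- suppressWarnings(
        glmnet::cv.glmnet(Z, y_min, family = "binomial", alpha = 0,
                          weights = w, foldid = foldid,
                          standardize = FALSE))
      lambda <- cvfit$lambda.min
    }
    fit <- glmnet::glmnet(Z, y_min, family = "binomial", alpha = 0,
                          lambda = lambda, weights = w,
                          standardize = FALSE)
    co <- as.numeric(stats::coef(fit))
  } else {
    df <- data.frame(z = Z[, 1], y = y_min)
    fit <- suppressWarnings(stats::glm(y ~ z, data = df, weights = w,
                                       family = stats::binomial()))
    co <- as.numeric(stats::coef(fit))
    co[is.na(co)] <- 0
  }
  list(intercept = co[1], weights = co[-1], lambda = lambda)
}

meta_predict <- function(meta, Z) {
  as.numeric(stats::plogis(meta$intercept + Z %*% meta$weights))
}

#' Out-of-fold probability matrix for a classifier pool
#'
#' For every pool member, fits the classifier on each training fold of a
#' stratified K-fold split and predicts the held-out fold, assembling an
#' `n x 10` matrix of out-of-fold minority-class probabilities. This
#' matrix is the second-layer design matrix of the stack, and because it
#' is computed once per dataset it lets the genetic algorithm (and an
#' exhaustive search) score any chromosome by refitting only the cheap
#' meta-learner.
#'
#' @param dataset an [imb_dataset].
#' @param pool an [classifier_pool()]; default [default_pool()].
#' @param cv_folds number of stratified folds (default 5).
#' @param seed integer seed controlling fold assignment and learner RNG.
#' @param members optional character/integer subset of pool members to
#'   compute (others left `NA`).
#' @param groups optional fold-grouping vector (see [stratified_folds()]).
#' @param resample optional list with elements `m` and `target_ratio`
#'   (and optionally `policy`): when given, `dataset` is treated as
#'   *unsampled* data and [amom_dums()] is applied inside each training
#'   fold before fitting, so the held-out predictions — always on real
#'   rows — are untouched by oversampling. This is the leak-free way to
#'   cross-validate a resampled pipeline.
#' @return list with `oof` (matrix, columns named by member id), `folds`
#'   (fold id per row), `y` (labels).
#' @export
pool_oof_matrix <- function(dataset, pool = default_pool(), cv_folds = 5L,
                            seed = NULL, members = NULL, groups = NULL,
                            resample = NULL) {
  stopifnot(inherits(dataset, "imb_dataset"),
            inherits(pool, "imb_classifier_pool"))
  folds <- stratified_folds(dataset$y, cv_folds, seed = derive_seed(seed, 1),
                            groups = groups)
  ids <- names(pool)
  use <- if (is.null(members)) {
    ids
  } else if (is.character(members)) {
    intersect(ids, members)
  } else {
    ids[members]
  }
  # per-fold training data, oversampled inside the fold when requested
  fold_train <- lapply(seq_len(cv_folds), function(f) {
    tr <- folds != f
    tr_ds <- imb_dataset(dataset$X[tr, , drop = FALSE], dataset$y[tr],
                         dataset$feature_names)
    if (is.null(resample)) return(tr_ds)
    amom_dums(tr_ds, m = resample$m %||% 5L,
              target_ratio = resample$target_ratio %||% 1.0,
              seed = derive_seed(seed, 300L + f),
              policy = resample$policy %||% "majority")$dataset
  })
  oof <- matrix(NA_real_, nrow(dataset$X), length(ids),
                dimnames = list(NULL, ids))
  for (id in use) {
    spec <- pool[[id]]
    for (f in seq_len(cv_folds)) {
      tr_ds <- fold_train[[f]]
      fit <- fit_classifier(spec, tr_ds$X, tr_ds$y,
                            seed = derive_seed(seed, 1000L * f + match(id, ids)))
      oof[folds == f, id] <- predict_minority_prob(
        fit, dataset$X[folds == f, , drop = FALSE])
    }
  }
  list(oof = oof, folds = folds, y = dataset$y)
}

#' Cross-validated AUC of a stacked combination
#'
#' Fitness of a chromosome given a precomputed out-of-fold matrix: the
#' meta-learner is itself cross-validated over the same folds (fit on the
#' selected out-of-fold columns of the training folds, predict the held
#' fold) and the pooled held-out predictions are scored by AUC of the
#' minority class. Deterministic given `oof` and `folds`.
#'
#' @param oof out-of-fold matrix from [pool_oof_matrix()].
#' @param y integer 0/1 labels.
#' @param bits chromosome bit vector (length `ncol(oof)`), or a logical
#'   selection.
#' @param folds fold assignment used to build `oof`.
#' @param metric `"auc"` (default) or `"accuracy"` at threshold 0.5.
#' @param eval_mask optional logical vector: rows to include when the
#'   metric is computed (predictions are still made for every row).
#'   Resampled pipelines pass the original-row mask so fitness is never
#'   scored on synthetic points.
#' @return a single numeric fitness in `[0, 1]`.
#' @export
stack_cv_auc <- function(oof, y, bits, folds, metric = c("auc", "accuracy"),
                         eval_mask = NULL) {
  metric <- match.arg(metric)
  if (is.null(eval_mask)) eval_mask <- rep(TRUE, length(y))
  sel <- which(as.logical(bits))
  if (length(sel) == 0L) stop("chromosome selects no classifier",
                              call. = FALSE)
  Z <- oof[, sel, drop = FALSE]
  if (anyNA(Z)) stop("out-of-fold matrix has missing columns for the ",
                     "selected members", call. = FALSE)
  pred <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    meta <- meta_fit(Z[tr, , drop = FALSE], y[tr])
    pred[!tr] <- meta_predict(meta, Z[!tr, , drop = FALSE])
  }
  if (metric == "auc") {
    auc(y[eval_mask], pred[eval_mask], positive_label = 0L)
  } else {
    mean((pred[eval_mask] >= 0.5) == (y[eval_mask] == 0L))
  }
}

#' Fit a two-layer stacked ensemble
#'
#' Builds the stack for one chromosome: out-of-fold minority-class
#' probabilities of each selected first-layer classifier form the
#' second-layer design matrix; a ridge-regularized logistic meta-learner
#' is fit on it; and each selected classifier is refit on the full data
#' for deployment.
#'
#' @param dataset an [imb_dataset] (typically resampled and
#'   feature-selected training data).
#' @param chromosome bit vector of length 10 over the pool; at least one
#'   bit set. Default: all ones (full pool).
#' @param pool an [classifier_pool()].
#' @param cv_folds stratified folds for the out-of-fold construction
#'   (default 5); minority count must be at least `cv_folds`.
#' @param seed integer seed (folds + learner RNG).
#' @param oof optional precomputed [pool_oof_matrix()] result to reuse.
#' @param groups optional fold-grouping vector (see [stratified_folds()]).
#' @param eval_mask optional logical row mask for the reported
#'   cross-validated AUC (see [stack_cv_auc()]).
#' @return object of class `imb_stack_model` with elements
#'   `selected_ids`, `first_layer` (fitted classifiers), `meta`
#'   (intercept/weights), `cv_folds`, `feature_names`, `oof_auc` (the
#'   chromosome's cross-validated fitness), `chromosome`.
#' @export
fit_stack <- function(dataset, chromosome = rep(1L, 10L),
                      pool = default_pool(), cv_folds = 5L, seed = NULL,
                      oof = NULL, groups = NULL, eval_mask = NULL) {
  stopifnot(inherits(dataset, "imb_dataset"))
  chromosome <- as.integer(chromosome)
  if (length(chromosome) != length(pool) || !all(chromosome %in% c(0L, 1L))) {
    stop("chromosome must be a 0/1 vector of length ", length(pool),
         call. = FALSE)
  }
  if (sum(chromosome) == 0L) {
    stop("chromosome selects no classifier; at least one bit must be set",
         call. = FALSE)
  }
  sel_ids <- names(pool)[chromosome == 1L]
  if (is.null(oof)) {
    oof <- pool_oof_matrix(dataset, pool, cv_folds, seed, members = sel_ids,
                           groups = groups)
  }
  # the OOF matrix may cover different rows than `dataset` (e.g. original
  # rows when the first layer is deployed on oversampled data), so the
  # meta-learner is trained against the labels that accompany it
  Z <- oof$oof[, sel_ids, drop = FALSE]
  meta <- meta_fit(Z, oof$y)
  fits <- lapply(sel_ids, function(id) {
    fit_classifier(pool[[id]], dataset$X, dataset$y,
                   seed = derive_seed(seed, 5000L + match(id, names(pool))))
  })
  names(fits) <- sel_ids
  structure(list(selected_ids = sel_ids,
                 first_layer = fits,
                 meta = meta,
                 cv_folds = as.integer(cv_folds),
                 feature_names = dataset$feature_names,
                 oof_auc = stack_cv_auc(oof$oof, oof$y, chromosome,
                                        oof$folds, eval_mask = eval_mask),
                 chromosome = chromosome,
                 oof = oof$oof[, sel_ids, drop = FALSE]),
            class = "imb_stack_model")
}

#' Predict minority-class probabilities from a stacked model
#'
#' Each selected first-layer classifier scores the new rows; the logistic
#' meta-learner maps the score vector `u` to
#' `P(v = 1 | u) = 1 / (1 + exp(-w'u))`, reported for the minority class.
#'
#' @param object an `imb_stack_model`.
#' @param X feature matrix with the columns the stack was trained on.
#' @param ... unused.
#' @return probability vector in `(0, 1)`.
#' @export
predict.imb_stack_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$feature_names)) {
    stop("expected ", length(object$feature_names), " feature columns (",
         paste(object$feature_names, collapse = ", "), "); got ", ncol(X),
         call. = FALSE)
  }
  Z <- vapply(object$first_layer, function(f) predict_minority_prob(f, X),
              numeric(nrow(X)))
  Z <- matrix(Z, nrow = nrow(X))
  meta_predict(object$meta, Z)
}

#' @export
print.imb_stack_model <- function(x, ...) {
  cat("<imb_stack_model> first layer:",
      paste(x$selected_ids, collapse = " + "),
      sprintf("\n  cross-validated AUC %.3f (%d folds)\n",
              x$oof_auc, x$cv_folds))
  invisible(x)
}
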