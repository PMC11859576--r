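#' Define a first-layer classifier
#'
#' A classifier spec is the unit the stacking layer and the genetic
#' algorithm operate on: an identifier, a fit function, a function mapping
#' a fitted model and a feature matrix to minority-class probabilities in
#' `[0, 1]`, a hyperparameter grid for [grid_search()], and default
#' parameters.
#'
#' @param id short unique identifier string.
#' @param fit `function(X, y, params)` returning a fitted model; `X` is a
#'   numeric matrix, `y` an integer 0/1 vector (0 = minority).
#' @param predict_prob `function(model, X)` returning `P(y = 0)` per row,
#'   values in `[0, 1]`.
#' @param grid named list of candidate hyperparameter vectors (may be
#'   empty).
#' @param default_params named list of default hyperparameters.
#' @param label human-readable name.
#' @return object of class `imb_classifier_spec`.
#' @export
classifier_spec <- function(id, fit, predict_prob, grid = list(),
                            default_params = list(), label = id) {
  stopifnot(is.character(id), length(id) == 1L,
            is.function(fit), is.function(predict_prob), is.list(grid))
  structure(list(id = id, label = label, fit = fit,
                 predict_prob = predict_prob, grid = grid,
                 default_params = default_params),
            class = "imb_classifier_spec")
}

#' Fit a classifier spec
#'
#' @param spec an [classifier_spec()] object.
#' @param X numeric feature matrix.
#' @param y integer 0/1 labels (0 = minority).
#' @param params hyperparameters; defaults to the spec's
#'   `default_params`.
#' @param seed optional seed isolating any RNG the learner uses.
#' @return object of class `imb_fitted_classifier`.
#' @export
fit_classifier <- function(spec, X, y, params = NULL, seed = NULL) {
  stopifnot(inherits(spec, "imb_classifier_spec"))
  params <- utils::modifyList(spec$default_params,
                              if (is.null(params)) list() else params)
  model <- with_seed(seed, spec$fit(X, y, params))
  structure(list(spec = spec, model = model, params = params,
                 feature_names = colnames(X)),
            class = "imb_fitted_classifier")
}

#' Minority-class probabilities from a fitted classifier
#'
#' @param object an `imb_fitted_classifier`.
#' @param X feature matrix with the columns the model was trained on.
#' @param ... unused.
#' @return numeric vector of `P(y = 0)` in `[0, 1]`.
#' @export
predict_minority_prob <- function(object, X, ...) {
  stopifnot(inherits(object, "imb_fitted_classifier"))
  X <- as.matrix(X)
  if (!is.null(object$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names)) {
    stop("feature columns do not match the model; expected: ",
         paste(object$feature_names, collapse = ", "), call. = FALSE)
  }
  p <- object$spec$predict_prob(object$model, X)
  pmin(pmax(as.numeric(p), 0), 1)
}

## ---- AdaBoost.M1 on decision stumps -------------------------------------
## Boosting member of the pool. Weak learners are depth-limited rpart trees
## fitted to reweighted data; the ensemble score is the weighted additive
## combination sum_z alpha_z * h_z(x), h_z in {-1, +1}, exposed stage by
## stage so the cumulative-combination property is testable.

adaboost_fit <- function(X, y, n_rounds = 50L, maxdepth = 1L) {
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X), unique = TRUE)
  t <- ifelse(y == 0L, 1, -1)  # minority coded +1
  n <- length(t)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, minsplit = 2,
                               minbucket = 1, xval = 0)
  dat <- cbind(df, .t = factor(t, levels = c(-1, 1)))
  for (z in seq_len(n_rounds)) {
    fitz <- rpart::rpart(.t ~ ., data = dat, weights = w, method = "class",
                         control = ctrl)
    h <- as.numeric(as.character(predict(fitz, df, type = "class")))
    err <- sum(w * (h != t))
    if (err >= 0.5) break           # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fitz
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * t * h)
    w <- w / sum(w)
    if (err <= 1e-10) break         # perfect stump: nothing left to learn
  }
  if (length(stumps) == 0L) {
    # degenerate: fall back to the weighted class prior
    prior <- (sum(y == 0L) + 1) / (n + 2)
    return(structure(list(stumps = list(), alphas = numeric(0),
                          prior = prior, cols = names(df)),
                     class = "imb_adaboost"))
  }
  structure(list(stumps = stumps, alphas = alphas, prior = NULL,
                 cols = names(df)),
            class = "imb_adaboost")
}

# n x Z matrix of cumulative weighted scores D_z(u) = D_{z-1}(u) +
# alpha_z h_z(u); column Z is the final ensemble score.
adaboost_staged_scores <- function(model, X) {
  df <- as.data.frame(X)
  names(df) <- model$cols
  Z <- length(model$stumps)
  if (Z == 0L) return(matrix(0, nrow(df), 0))
  H <- vapply(model$stumps, function(s) {
    as.numeric(as.character(predict(s, df, type = "class")))
  }, numeric(nrow(df)))
  H <- matrix(H, nrow = nrow(df))
  staged <- H %*% diag(model$alphas, Z)
  t(apply(staged, 1, cumsum))
}

adaboost_prob <- function(model, X) {
  if (length(model$stumps) == 0L) return(rep(model$prior, nrow(X)))
  sc <- adaboost_staged_scores(model, X)
  stats::plogis(2 * sc[, ncol(sc)])
}

## ---- deterministic RBF bandwidth ----------------------------------------
## Median-pairwise-squared-distance heuristic on (at most) 200 rows taken
## at fixed strides, so no RNG is consumed.
median_rbf_sigma <- function(X) {
  n <- nrow(X)
  idx <- if (n > 200) round(seq(1, n, length.out = 200)) else seq_len(n)
  d2 <- cross_dist2(X[idx, , drop = FALSE], X[idx, , drop = FALSE])
  d2 <- d2[upper.tri(d2)]
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) return(1)
  1 / med
}

## ---- the default 10-learner pool ----------------------------------------

pool_member_svm <- function(profile) {
  classifier_spec(
    id = "svm", label = "support vector machine (RBF)",
    fit = function(X, y, params) {
      e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = params$cost, gamma = params$gamma %||% (1 / ncol(X)),
                 scale = FALSE)
    },
    predict_prob = function(model, X) {
      dv <- attr(predict(model, X, decision.values = TRUE),
                 "decision.values")
      v <- dv[, 1]
      # decision values are signed margins for the level named first
      if (!startsWith(colnames(dv)[1], "0/")) v <- -v
      stats::plogis(v)
    },
    grid = list(cost = c(0.1, 1, 10)),
    default_params = list(cost = 1, gamma = NULL))
}

pool_member_adaboost <- function(profile) {
  nr <- if (profile == "fast") 30L else 60L
  classifier_spec(
    id = "adaboost", label = "AdaBoost (decision stumps)",
    fit = function(X, y, params) {
      adaboost_fit(X, y, n_rounds = params$n_rounds,
                   maxdepth = params$maxdepth)
    },
    predict_prob = function(model, X) adaboost_prob(model, X),
    grid = list(n_rounds = c(30L, 60L, 120L)),
    default_params = list(n_rounds = nr, maxdepth = 1L))
}

pool_member_rf <- function(profile) {
  nt <- if (profile == "fast") 60L else 200L
  classifier_spec(
    id = "rf", label = "random forest",
    fit = function(X, y, params) {
      randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                 ntree = params$ntree, mtry = params$mtry %||%
                                   max(1L, floor(sqrt(ncol(X)))))
    },
    predict_prob = function(model, X) predict(model, X, type = "prob")[, "0"],
    grid = list(ntree = c(100L, 200L)),
    default_params = list(ntree = nt, mtry = NULL))
}

pool_member_bagging <- function(profile) {
  nt <- if (profile == "fast") 40L else 100L
  classifier_spec(
    id = "bagging", label = "bagged trees",
    fit = function(X, y, params) {
      # bagging = forest with all features considered at every split
      randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                 ntree = params$ntree, mtry = ncol(X))
    },
    predict_prob = function(model, X) predict(model, X, type = "prob")[, "0"],
    grid = list(ntree = c(50L, 100L)),
    default_params = list(ntree = nt))
}

xgb_fit <- function(X, y, nrounds, max_depth, eta) {
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y == 0L))
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   max_depth = max_depth, eta = eta,
                                   nthread = 1),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

xgb_prob <- function(model, X) {
  predict(model, xgboost::xgb.DMatrix(X))
}

pool_member_gbdt <- function(profile) {
  nr <- if (profile == "fast") 40L else 80L
  classifier_spec(
    id = "gbdt", label = "gradient-boosted trees",
    fit = function(X, y, params) {
      xgb_fit(X, y, params$nrounds, params$max_depth, params$eta)
    },
    predict_prob = function(model, X) xgb_prob(model, X),
    grid = list(max_depth = c(2L, 3L, 4L)),
    default_params = list(nrounds = nr, max_depth = 3L, eta = 0.3))
}

pool_member_egb <- function(profile) {
  nr <- if (profile == "fast") 60L else 150L
  classifier_spec(
    id = "egb", label = "extreme gradient boosting (deep, slow-rate)",
    fit = function(X, y, params) {
      xgb_fit(X, y, params$nrounds, params$max_depth, params$eta)
    },
    predict_prob = function(model, X) xgb_prob(model, X),
    grid = list(eta = c(0.05, 0.1, 0.3)),
    default_params = list(nrounds = nr, max_depth = 5L, eta = 0.1))
}

pool_member_nb <- function(profile) {
  classifier_spec(
    id = "nb", label = "Gaussian naive Bayes",
    fit = function(X, y, params) {
      e1071::naiveBayes(as.data.frame(X), factor(y, levels = c(0, 1)))
    },
    predict_prob = function(model, X) {
      predict(model, as.data.frame(X), type = "raw",
              threshold = 1e-3, eps = 1e-6)[, "0"]
    })
}

pool_member_gp <- function(profile) {
  cap <- if (profile == "fast") 250L else 400L
  classifier_spec(
    id = "gp", label = "Gaussian process classifier (RBF, probit link)",
    fit = function(X, y, params) {
      # subset-of-data approximation: GP training is O(n^3)
      n <- nrow(X)
      idx <- if (n > params$max_train) {
        with_seed(1L, c(sample(which(y == 0L),
                               min(sum(y == 0L), ceiling(params$max_train / 2))),
                        sample(which(y == 1L),
                               min(sum(y == 1L), ceiling(params$max_train / 2)))))
      } else seq_len(n)
      Xs <- X[idx, , drop = FALSE]
      sig <- params$sigma %||% median_rbf_sigma(Xs)
      suppressMessages(
        kernlab::gausspr(Xs, factor(y[idx], levels = c(0, 1)),
                         kernel = "rbfdot", kpar = list(sigma = sig),
                         var = params$noise_var))
    },
    predict_prob = function(model, X) {
      kernlab::predict(model, X, type = "probabilities")[, "0"]
    },
    grid = list(noise_var = c(0.01, 0.1, 1)),
    default_params = list(noise_var = 0.1, sigma = NULL, max_train = cap))
}

pool_member_logit <- function(profile) {
  classifier_spec(
    id = "logit", label = "logistic regression",
    fit = function(X, y, params) {
      df <- as.data.frame(X); names(df) <- paste0("V", seq_len(ncol(X)))
      df$.y <- as.numeric(y == 0L)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    predict_prob = function(model, X) {
      df <- as.data.frame(X); names(df) <- paste0("V", seq_len(ncol(X)))
      suppressWarnings(stats::predict(model, df, type = "response"))
    })
}

pool_member_knn <- function(profile) {
  classifier_spec(
    id = "knn", label = "k-nearest neighbours",
    fit = function(X, y, params) list(X = X, y = y, k = params$k),
    predict_prob = function(model, X) {
      pr <- class::knn(model$X, X, factor(model$y, levels = c(0, 1)),
                       k = model$k, prob = TRUE)
      votes <- attr(pr, "prob")
      ifelse(pr == "0", votes, 1 - votes)
    },
    grid = list(k = c(3L, 5L, 9L)),
    default_params = list(k = 7L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The default heterogeneous 10-classifier pool
#'
#' First-layer panel of the stacked ensemble: support vector machine,
#' AdaBoost, random forest, bagged trees, two gradient-boosting variants,
#' Gaussian naive Bayes, a Gaussian-process classifier, logistic
#' regression and k-nearest neighbours. The pool is an ordered list of 10
#' [classifier_spec()] objects and is fully replaceable; the chromosome
#' bitstring indexes into it positionally.
#'
#' @param profile `"default"` for full-size learners, `"fast"` for
#'   smaller ensembles/tree counts when wall-clock matters more than the
#'   last fraction of AUC.
#' @return object of class `imb_classifier_pool` (a list of 10 specs).
#' @export
default_pool <- function(profile = c("default", "fast")) {
  profile <- match.arg(profile)
  classifier_pool(list(
    pool_member_svm(profile), pool_member_adaboost(profile),
    pool_member_rf(profile), pool_member_bagging(profile),
    pool_member_gbdt(profile), pool_member_egb(profile),
    pool_member_nb(profile), pool_member_gp(profile),
    pool_member_logit(profile), pool_member_knn(profile)))
}

#' Assemble a classifier pool
#'
#' @param specs list of exactly 10 [classifier_spec()] objects with
#'   unique ids (the chromosome length is fixed at 10).
#' @return object of class `imb_classifier_pool`.
#' @export
classifier_pool <- function(specs) {
  stopifnot(is.list(specs))
  if (length(specs) != 10L) {
    stop("a classifier pool must have exactly 10 members (got ",
         length(specs), ")", call. = FALSE)
  }
  ok <- vapply(specs, inherits, logical(1), "imb_classifier_spec")
  if (!all(ok)) stop("all pool members must be classifier_spec objects",
                     call. = FALSE)
  ids <- vapply(specs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("pool member ids must be unique", call. = FALSE)
  names(specs) <- ids
  structure(specs, class = "imb_classifier_pool")
}

#' @export
print.imb_classifier_pool <- function(x, ...) {
  cat("<imb_classifier_pool> 10 members:\n")
  for (s in x) cat("  -", s$id, ":", s$label, "\n")
  invisible(x)
}
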