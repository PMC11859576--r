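make_stack_fixture <- function(seed = 10, n1 = 90, n0 = 45) {
  scenario_generate(scenario_config(n_majority = n1, n_minority = n0,
                                    n_informative = 3, n_redundant = 2,
                                    n_noise = 2, class_separation = 1.5,
                                    rng_seed = seed))
}

test_that("out-of-fold construction is deterministic and fold-complete", {
  d <- make_stack_fixture()
  pool <- cheap_test_pool()
  o1 <- pool_oof_matrix(d, pool, cv_folds = 4, seed = 2)
  o2 <- pool_oof_matrix(d, pool, cv_folds = 4, seed = 2)
  expect_identical(o1$oof, o2$oof)
  expect_identical(o1$folds, o2$folds)
  expect_false(anyNA(o1$oof))
  expect_setequal(unique(o1$folds), 1:4)
  # folds are stratified: every fold holds both classes
  for (f in 1:4) expect_setequal(unique(d$y[o1$folds == f]), c(0L, 1L))
})

test_that("a single-member stack matches that member's own cross-validated AUC", {
  d <- make_stack_fixture()
  pool <- cheap_test_pool()
  oof <- pool_oof_matrix(d, pool, cv_folds = 4, seed = 2)
  bits <- c(1L, rep(0L, 9))
  stack_auc <- stack_cv_auc(oof$oof, oof$y, bits, oof$folds)
  member_auc <- auc(d$y, oof$oof[, 1], positive_label = 0L)
  expect_equal(stack_auc, member_auc, tolerance = 0.03)
})

test_that("a first-layer column equal to the labels drives training AUC to 1", {
  d <- make_stack_fixture()
  oof <- matrix(runif(nrow(d$X) * 10), ncol = 10)
  oof[, 4] <- as.numeric(d$y == 0L)  # perfect oracle column
  folds <- stratified_folds(d$y, 4, seed = 1)
  expect_equal(stack_cv_auc(oof, d$y, c(0, 0, 0, 1, rep(0, 6)), folds), 1)
  expect_gte(stack_cv_auc(oof, d$y, rep(1, 10), folds), 0.99)
})

test_that("fitted stacks validate chromosomes, predict in (0,1), and survive serialization", {
  d <- make_stack_fixture()
  pool <- cheap_test_pool()
  expect_error(fit_stack(d, rep(0L, 10), pool), "at least one")
  expect_error(fit_stack(d, c(1, 1), pool), "length 10")

  st <- fit_stack(d, c(1L, 1L, 0L, 1L, rep(0L, 6)), pool, cv_folds = 4,
                  seed = 3)
  expect_equal(st$selected_ids, c("sig1", "sig2", "noise2"))
  p <- predict(st, d$X)
  expect_true(all(p > 0 & p < 1))

  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(st, path)
  st2 <- readRDS(path)
  expect_identical(predict(st2, d$X), p)

  expect_error(predict(st, d$X[, 1:3]), "feature")
})

test_that("meta-learner columns are genuinely out-of-fold: permuted labels score near 0.5", {
  d <- make_stack_fixture(seed = 23, n1 = 300, n0 = 300)
  set.seed(99)
  y_perm <- sample(d$y)
  d_perm <- imb_dataset(d$X, y_perm, d$feature_names)
  oof <- pool_oof_matrix(d_perm, cheap_test_pool(), cv_folds = 4, seed = 5)
  fit <- stack_cv_auc(oof$oof, oof$y, rep(1L, 10), oof$folds)
  expect_lt(abs(fit - 0.5), 0.05)
})

test_that("grid search enumerates the full Cartesian product and picks the best setting", {
  d <- make_stack_fixture()
  # param p = 1 uses the informative feature, p = 0 outputs a constant
  spec <- classifier_spec(
    id = "toggle",
    fit = function(X, y, params) {
      if (params$p == 0) return(NULL)
      df <- data.frame(x = X[, 1], y = as.numeric(y == 0))
      suppressWarnings(glm(y ~ x, data = df, family = binomial()))
    },
    predict_prob = function(model, X) {
      if (is.null(model)) return(rep(0.5, nrow(X)))
      suppressWarnings(predict(model, data.frame(x = X[, 1]),
                               type = "response"))
    },
    grid = list(p = c(0, 1), q = c("a", "b")))
  gs <- grid_search(spec, d, cv_folds = 3, seed = 1)
  expect_equal(gs$n_combinations, 4)
  expect_equal(nrow(gs$results), 4)
  expect_equal(gs$best_params$p, 1)
  # deterministic tie-break: both q values tie at p = 1, first enumerated wins
  expect_equal(gs$best_params$q, "a")

  one <- grid_search(spec, d, param_grid = list(p = 1), cv_folds = 3)
  expect_equal(one$best_params$p, 1)
  expect_error(grid_search(spec, d, param_grid = list()), "empty")
})
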