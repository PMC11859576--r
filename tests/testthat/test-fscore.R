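test_that("both F-score variants match direct-summation evaluation on the 6-sample fixture", {
  # majority (n+): 2, 3, 4; minority (n-): 0, 0, 1
  d <- imb_dataset(matrix(c(0, 0, 1, 2, 3, 4), 6, 1),
                   c(0, 0, 0, 1, 1, 1))
  expect_equal(fscore_standard(d, 1), 8 / 3, tolerance = 1e-12)
  expect_equal(fscore_improved(d, 1), 32 / 9, tolerance = 1e-12)
  expect_equal(fscore_standard(d, 1), oracle_fscore(d$X[, 1], d$y, FALSE),
               tolerance = 1e-14)
  expect_equal(fscore_improved(d, 1), oracle_fscore(d$X[, 1], d$y, TRUE),
               tolerance = 1e-14)
})

test_that("implementations agree with the formula oracle on random fixtures", {
  set.seed(33)
  for (rep in 1:30) {
    n0 <- sample(2:8, 1); n1 <- sample(2:12, 1)
    v <- rnorm(n0 + n1)
    y <- rep(c(0L, 1L), c(n0, n1))
    d <- imb_dataset(matrix(v), y)
    expect_equal(fscore_standard(d, 1), oracle_fscore(v, y, FALSE),
                 tolerance = 1e-12)
    expect_equal(fscore_improved(d, 1), oracle_fscore(v, y, TRUE),
                 tolerance = 1e-12)
    # smaller denominator: improved >= standard whenever minority varies
    if (var(v[y == 0L]) > 0) {
      expect_gte(fscore_improved(d, 1), fscore_standard(d, 1))
    }
  }
})

test_that("degenerate features are flagged rather than scored", {
  d <- imb_dataset(cbind(const = rep(2, 6), lab = c(0, 0, 0, 1, 1, 1)),
                   c(0, 0, 0, 1, 1, 1))
  expect_equal(fscore_standard(d, "const"), 0)
  expect_warning(v <- fscore_standard(d, "lab"), "Inf")
  expect_equal(v, Inf)
  # minority arbitrary, majority constant -> improved flagged Inf
  d2 <- imb_dataset(matrix(c(0.3, 1.2, -1, 5, 5, 5), 6, 1),
                    c(0, 0, 0, 1, 1, 1))
  expect_warning(vi <- fscore_improved(d2, 1), "Inf")
  expect_equal(vi, Inf)
  tiny <- imb_dataset(matrix(1:3), c(0, 1, 1))
  expect_error(fscore_standard(tiny, 1), ">= 2 samples")
})

test_that("scores are invariant under adding a constant to the feature", {
  set.seed(8)
  v <- rnorm(30); y <- rep(c(0L, 1L), 15)
  d1 <- imb_dataset(matrix(v), y)
  d2 <- imb_dataset(matrix(v + 17.3), y)
  expect_equal(fscore_standard(d1, 1), fscore_standard(d2, 1),
               tolerance = 1e-10)
  expect_equal(fscore_improved(d1, 1), fscore_improved(d2, 1),
               tolerance = 1e-10)
})

test_that("ranking puts signal first, breaks ties by column order, and is permutation-equivariant", {
  set.seed(12)
  y <- rep(c(0L, 1L), c(20, 40))
  X <- cbind(sig = ifelse(y == 0L, 2, 0) + rnorm(60, sd = 0.4),
             ns1 = rnorm(60), ns2 = rnorm(60))
  d <- imb_dataset(X, y)
  rk <- rank_features(d)
  expect_equal(rk$feature_name[1], "sig")
  expect_setequal(rk$rank, 1:3)

  same <- imb_dataset(cbind(a = rep(1, 6), b = rep(1, 6), c = rep(1, 6)),
                      c(0, 0, 0, 1, 1, 1))
  expect_equal(rank_features(same)$feature_name, c("a", "b", "c"))

  perm <- imb_dataset(X[, c(2, 3, 1)], y)
  rkp <- rank_features(perm)
  expect_equal(rkp$feature_name[1], "sig")
  m <- merge(rk, rkp, by = "feature_name")
  expect_equal(m$rank.x, m$rank.y)
})

test_that("the wrapper recovers a planted subset with an inverted-U AUC profile", {
  d <- scenario_generate(scenario_config(
    n_majority = 160, n_minority = 60, n_informative = 3, n_redundant = 0,
    n_noise = 17, class_separation = 2, rng_seed = 17))
  wr <- wrapper_select(d, classifier = "logit", max_dim = 20, cv_folds = 5,
                       seed = 5)
  planted <- paste0("inf", 1:3)
  expect_true(all(planted %in% wr$scores$feature_name[1:5]))
  expect_true(wr$best_dimension %in% 2:6)
  expect_true(all(planted %in% wr$selected_features) ||
                wr$best_dimension < 3)
  peak <- max(wr$auc_by_dimension)
  expect_lte(wr$auc_by_dimension[1], peak)
  expect_lte(wr$auc_by_dimension[20], peak)
  # selecting only the signal should beat using everything
  expect_gte(peak, wr$baseline_auc_no_fs - 0.02)
})

test_that("wrapper edge cases behave per contract", {
  d <- scenario_generate(scenario_config(n_majority = 40, n_minority = 12,
                                         n_informative = 2, n_redundant = 0,
                                         n_noise = 2, rng_seed = 3))
  wr <- wrapper_select(d, classifier = "logit", max_dim = 1, cv_folds = 3,
                       seed = 1)
  expect_length(wr$auc_by_dimension, 1)
  expect_equal(wr$best_dimension, 1L)
  expect_error(wrapper_select(d, max_dim = 99), "max_dim")
  expect_error(wrapper_select(d, cv_folds = 13, classifier = "logit"),
               "folds")
})
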