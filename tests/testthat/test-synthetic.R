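test_that("presets reproduce the benchmark cohort shapes", {
  a <- scenario_preset("tableA"); b <- scenario_preset("tableB")
  c3 <- scenario_preset("tableC"); p <- scenario_preset("pih1")
  expect_equal(c(a$n_minority, a$n_majority), c(392L, 1695L))
  expect_equal(c(b$n_minority, b$n_majority), c(86L, 2008L))
  expect_equal(c(c3$n_minority, c3$n_majority), c(122L, 1958L))
  expect_equal(c(p$n_minority, p$n_majority), c(42L, 2136L))
  expect_equal(p$n_informative + p$n_redundant + p$n_noise, 25L)

  dp <- scenario_generate(scenario_preset("pih1", rng_seed = 1))
  expect_equal(ncol(dp$X), 25)
  expect_equal(round(compute_ur(dp), 2), 50.86)
  db <- scenario_generate(scenario_preset("tableB", rng_seed = 1))
  expect_equal(round(compute_ur(db), 3), 23.349)

  expect_error(scenario_preset("tableZ"), "tableA")
})

test_that("generation is deterministic under seed and shapes follow the config", {
  cfg <- scenario_config(n_majority = 50, n_minority = 20,
                         n_informative = 2, n_redundant = 3, n_noise = 1,
                         derived_ratio_feature = TRUE, rng_seed = 77)
  d1 <- scenario_generate(cfg)
  d2 <- scenario_generate(cfg)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$y, d2$y)
  expect_equal(ncol(d1$X), 2 + 3 + 1 + 1)
  expect_true("ratio" %in% d1$feature_names)
  expect_true(all(is.finite(d1$X)))
})

test_that("with zero separation no classifier can beat chance", {
  d <- scenario_generate(scenario_config(n_majority = 200, n_minority = 200,
                                         class_separation = 0, rng_seed = 5))
  oof <- pool_oof_matrix(d, cheap_test_pool(1), cv_folds = 5, seed = 2)
  expect_lt(abs(auc(d$y, oof$oof[, 1], 0) - 0.5), 0.05)
})

test_that("configured class separation and redundancy correlation are realized empirically", {
  cfg <- scenario_config(n_majority = 1500, n_minority = 1500,
                         n_informative = 4, n_redundant = 4, n_noise = 0,
                         class_separation = 2, redundancy_rho = 0.6,
                         rng_seed = 42)
  d <- scenario_generate(cfg)
  mu0 <- colMeans(d$X[d$y == 0L, 1:4]); mu1 <- colMeans(d$X[d$y == 1L, 1:4])
  sep <- sqrt(sum((mu0 - mu1)^2))
  expect_lt(abs(sep - 2) / 2, 0.1)
  for (j in 1:4) {
    r <- cor(d$X[, j], d$X[, 4 + j])
    expect_lt(abs(r - 0.6), 0.05)
  }
})

test_that("improved-F-score ranking consistently surfaces the planted features", {
  hits <- 0L
  for (s in 1:20) {
    d <- scenario_generate(scenario_config(
      n_majority = 160, n_minority = 60, n_informative = 3,
      n_redundant = 0, n_noise = 17, class_separation = 2, rng_seed = s))
    top5 <- rank_features(d)$feature_name[1:5]
    if (all(paste0("inf", 1:3) %in% top5)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
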