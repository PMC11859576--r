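test_that("every synthetic point lies on a segment between two original minority samples", {
  d <- scenario_generate(scenario_config(n_majority = 60, n_minority = 12,
                                         n_informative = 2, n_redundant = 0,
                                         n_noise = 1, rng_seed = 11))
  res <- amom_oversample(d, m = 5, seed = 4)
  Xmin <- d$X[d$y == 0L, , drop = FALSE]
  synth <- res$dataset$X[res$synthetic_mask, , drop = FALSE]
  expect_gt(nrow(synth), 0)
  for (r in seq_len(nrow(synth))) {
    expect_true(oracle_on_some_segment(synth[r, ], Xmin, tol = 1e-9))
  }
  expect_true(all(res$dataset$y[res$synthetic_mask] == 0L))
  expect_true(all(res$dataset$provenance[res$synthetic_mask] ==
                    "synthetic_amom"))
})

test_that("two collinear minority points interpolate on their own segment", {
  X <- rbind(c(0, 0), c(1, 1), c(5, 0), c(6, 1), c(7, 0),
             c(8, 1), c(9, 0), c(10, 1))
  d <- imb_dataset(X, c(0, 0, 1, 1, 1, 1, 1, 1))
  res <- amom_oversample(d, m = 1, seed = 9)
  synth <- res$dataset$X[res$synthetic_mask, , drop = FALSE]
  # with only two minority points, every synthetic sample is on their segment
  for (r in seq_len(nrow(synth))) {
    expect_equal(unname(synth[r, 1]), unname(synth[r, 2]),
                 tolerance = 1e-12)
    expect_true(synth[r, 1] >= 0 && synth[r, 1] <= 1)
  }
})

test_that("oversampling reaches the target count and validates its inputs", {
  d <- scenario_generate(scenario_config(n_majority = 97, n_minority = 10,
                                         rng_seed = 2))
  res <- amom_oversample(d, m = 5, target_ratio = 1, seed = 1)
  expect_equal(sum(res$dataset$y == 0L), 97)  # ceil(1 * 97)
  half <- amom_oversample(d, m = 5, target_ratio = 0.5, seed = 1)
  expect_equal(sum(half$dataset$y == 0L), ceiling(0.5 * 97))

  expect_error(amom_oversample(d, m = 10), "m <= 9")
  expect_error(amom_oversample(d, m = 5, target_ratio = 1.5), "target_ratio")
  expect_warning(amom_oversample(d, m = 5, target_ratio = 0.1),
                 "already meets")
  one_class <- imb_dataset(matrix(rnorm(10), 5, 2), rep(1, 5))
  expect_error(amom_oversample(one_class, m = 2), "minority")
})

test_that("cleaning removes the known boundary point and only it", {
  # minority at 0.0; majority at 0.1 (mutual NN with it), 5.0 and 6.0
  d <- imb_dataset(matrix(c(0, 0.1, 5, 6), 4, 1), c(0, 1, 1, 1))
  expect_length(oracle_tomek_links(d$X, d$y), 1)
  res <- dums_clean(d)
  expect_equal(res$deleted_indices, 2L)
  expect_equal(nrow(res$dataset$X), 3)
  expect_equal(res$dataset$y, c(0L, 1L, 1L))
})

test_that("well-separated clusters are left untouched by cleaning", {
  set.seed(5)
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(40, 10, 0.1), 20))
  d <- imb_dataset(X, rep(c(0, 1), c(10, 20)))
  res <- dums_clean(d)
  expect_length(res$deleted_indices, 0)
  comp <- amom_dums(d, m = 3, seed = 1)
  expect_length(comp$deleted_indices, 0)
})

test_that("after cleaning the brute-force scan finds no remaining links", {
  for (s in 1:8) {
    d <- scenario_generate(scenario_config(
      n_majority = 80, n_minority = 40, n_informative = 2, n_redundant = 0,
      n_noise = 1, class_separation = 0.5, rng_seed = s))
    res <- dums_clean(d)
    expect_length(oracle_tomek_links(res$dataset$X, res$dataset$y), 0)
    expect_gte(res$iterations, 1)
  }
})

test_that("hybrid sampling is deterministic under a fixed seed and moves UR toward 1", {
  d <- scenario_generate(scenario_config(n_majority = 120, n_minority = 12,
                                         class_separation = 0.8,
                                         rng_seed = 21))
  r1 <- amom_dums(d, seed = 42)
  r2 <- amom_dums(d, seed = 42)
  expect_identical(r1$dataset$X, r2$dataset$X)
  expect_identical(r1$deleted_indices, r2$deleted_indices)
  expect_lt(abs(compute_ur(r1$dataset) - 1), abs(compute_ur(d) - 1))
})

test_that("cleaning never empties a class and rejects all-identical input", {
  d <- imb_dataset(matrix(c(0, 0.1, 5), 3, 1), c(0, 1, 1))
  w <- capture_warnings(res <- dums_clean(d, policy = "both"))
  expect_true(any(grepl("empty", w)))
  expect_true(all(c(0L, 1L) %in% res$dataset$y))
  same <- imb_dataset(matrix(1, 4, 1), c(0, 1, 0, 1))
  expect_error(dums_clean(same), "identical")
})
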