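test_that("unbalanced ratio matches the benchmark cohort values and flips under label swap", {
  cases <- list(c(392, 1695, 4.324), c(86, 2008, 23.349),
                c(122, 1958, 16.049))
  for (cs in cases) {
    d <- mk_counts_dataset(cs[1], cs[2])
    expect_equal(round(compute_ur(d), 3), cs[3])
    swapped <- imb_dataset(d$X, 1L - d$y)
    expect_equal(compute_ur(swapped), 1 / compute_ur(d))
  }
  expect_equal(round(compute_ur(mk_counts_dataset(42, 2136)), 2), 50.86)
  expect_equal(compute_ur(mk_counts_dataset(100, 100)), 1)
})

test_that("degenerate datasets are rejected with the class named", {
  expect_error(imb_dataset(matrix(0, 2, 1), c(0, 2)), "labels")
  d <- imb_dataset(matrix(0, 3, 1), c(1, 1, 1))
  expect_error(compute_ur(d), "minority")
  d0 <- imb_dataset(matrix(0, 3, 1), c(0, 0, 0))
  expect_error(compute_ur(d0), "majority")
  expect_error(imb_dataset(matrix(c(1, NA), 2, 1), c(0, 1)), "non-finite")
})

test_that("min-max normalization maps ranges to [0,1] with the degenerate-range convention", {
  d <- imb_dataset(cbind(a = c(2, 4, 6), b = c(3, 3, 3), c = c(1, 2, 10)),
                   c(0, 1, 1))
  expect_warning(res <- minmax_normalize(d), "constant")
  expect_equal(res$dataset$X[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(res$dataset$X[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(res$dataset$X[, "c"], c(0, 1 / 9, 1), ignore_attr = TRUE)
  expect_true(all(res$dataset$X >= 0 & res$dataset$X <= 1))
})

test_that("normalization is idempotent, rank-preserving, and reusable on held-out rows", {
  set.seed(7)
  d <- imb_dataset(matrix(rnorm(60, sd = 5), 20, 3), rep(c(0, 1), 10))
  n1 <- minmax_normalize(d)
  n2 <- minmax_normalize(n1$dataset)
  expect_equal(n1$dataset$X, n2$dataset$X, tolerance = 1e-12)
  for (j in 1:3) {
    expect_equal(order(d$X[, j]), order(n1$dataset$X[, j]))
  }
  held <- imb_dataset(d$X[1:5, ] / 2, d$y[1:5], d$feature_names)
  reap <- minmax_normalize(held, params = n1$params)
  expect_true(all(reap$dataset$X >= 0 & reap$dataset$X <= 1))
})

test_that("BMI is weight over height squared and rejects non-positive input", {
  expect_equal(derive_bmi(60, 1.6), 23.4375)
  expect_equal(derive_bmi(3.7, 1), 3.7)
  expect_error(derive_bmi(60, 0), "height")
  expect_error(derive_bmi(-1, 1.6), "weight")
})

test_that("season codes follow the spring=1..winter=4 month mapping", {
  expect_equal(derive_season(c(3, 6, 9, 12, 1)), c(1L, 2L, 3L, 4L, 4L))
  expect_error(derive_season(13), "month")
})

test_that("dataset CSV round-trips and bad files raise distinct errors", {
  d <- scenario_generate(scenario_config(n_majority = 20, n_minority = 8,
                                         rng_seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  back <- read_dataset(path)
  expect_equal(back$X, d$X, tolerance = 1e-12)
  expect_equal(back$y, d$y)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,label", "1,0", "2,2"), bad)
  expect_error(read_dataset(bad), "0 .*and 1|minority")
  expect_error(read_dataset(path, label_column = "outcome"), "outcome")
  expect_error(read_dataset("no/such/file.csv"), "not found")
})

test_that("missing-value policy drops sparse columns then incomplete rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(good = 1:10, holey = c(NA, NA, NA, 4:10),
                   label = rep(c(0, 1), 5))
  df$good[2] <- NA
  utils::write.csv(df, path, row.names = FALSE)
  expect_message(expect_message(d <- read_dataset(path), "holey"),
                 "missing")
  expect_equal(d$feature_names, "good")
  expect_equal(nrow(d$X), 9)
})
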