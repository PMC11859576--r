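chrom <- function(...) as.integer(c(...))

test_that("roulette selection follows fitness-proportional probabilities", {
  pop <- list(chrom(1, rep(0, 9)), chrom(0, 1, rep(0, 8)))
  sel <- roulette_select(pop, c(1, 3), n_select = 20000, seed = 2)
  frac_first <- mean(vapply(sel, function(b) b[1] == 1L, logical(1)))
  expect_lt(abs(frac_first - 0.25), 0.01)

  pop4 <- lapply(1:4, function(i) { b <- rep(0L, 10); b[i] <- 1L; b })
  sel4 <- roulette_select(pop4, c(1, 1, 1, 1), n_select = 20000, seed = 3)
  counts <- table(vapply(sel4, function(b) which(b == 1L), integer(1)))
  expect_true(all(abs(counts / 20000 - 0.25) < 0.02))

  expect_length(roulette_select(pop, c(1, 3), 0), 0)
  expect_warning(z <- roulette_select(pop, c(0, 0), 10, seed = 1),
                 "uniform")
  expect_length(z, 10)
})

test_that("multi-point crossover swaps blocks and conserves per-position bits", {
  a <- rep(1L, 10); b <- rep(0L, 10)
  kids <- multipoint_crossover(a, b, cuts = 5)
  expect_equal(kids$child_a, chrom(rep(1, 5), rep(0, 5)))
  expect_equal(kids$child_b, chrom(rep(0, 5), rep(1, 5)))

  same <- multipoint_crossover(a, a, crossover_points = 3, seed = 1)
  expect_equal(same$child_a, a)
  expect_equal(same$child_b, a)

  set.seed(44)
  for (rep in 1:25) {
    pa <- as.integer(runif(10) < 0.5); pb <- as.integer(runif(10) < 0.5)
    k <- multipoint_crossover(pa, pb,
                              crossover_points = sample(1:9, 1),
                              seed = rep)
    expect_equal(k$child_a + k$child_b, pa + pb)  # per-position multiset
  }
  expect_error(multipoint_crossover(a, b, crossover_points = 10),
               "below the chromosome length")
})

test_that("mutation flips bits at the configured rate and repairs empty chromosomes", {
  c0 <- chrom(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  expect_equal(multipoint_mutation(c0, 0, seed = 1), c0)
  expect_equal(multipoint_mutation(c0, 1, seed = 1), 1L - c0)
  # all-ones complement would be all-zero: repair must set one bit
  ones <- rep(1L, 10)
  rep1 <- multipoint_mutation(ones, 1, seed = 2)
  expect_equal(sum(rep1), 1)

  set.seed(7)
  flips <- replicate(20000, sum(multipoint_mutation(c0, 0.1) != c0))
  expect_lt(abs(mean(flips) - 1.0), 0.03)
})

test_that("the GA matches exhaustive enumeration on a pool with two informative members", {
  d <- scenario_generate(scenario_config(n_majority = 120, n_minority = 60,
                                         n_informative = 3, n_redundant = 0,
                                         n_noise = 2, class_separation = 1.5,
                                         rng_seed = 31))
  pool <- cheap_test_pool(n_signal = 2)
  oof <- pool_oof_matrix(d, pool, cv_folds = 4, seed = 8)
  ex <- exhaustive_stack_search(d, pool, oof = oof)
  ga <- ga_optimize(d, pool, ga_config(population_size = 20,
                                       generations = 12, rng_seed = 9),
                    oof = oof)
  expect_lte(ex$best_fitness - ga$best_fitness, 0.01)
  # the winning subset must include the informative members
  expect_true(all(ex$best_chromosome[1:2] == 1L))
  expect_true(all(diff(ga$history$best_ever) >= 0))
})

test_that("elitism guarantees the result is never worse than the initial best", {
  d <- scenario_generate(scenario_config(n_majority = 60, n_minority = 30,
                                         rng_seed = 3))
  pool <- cheap_test_pool()
  oof <- pool_oof_matrix(d, pool, cv_folds = 3, seed = 1)
  g0 <- ga_optimize(d, pool, ga_config(population_size = 6, generations = 0,
                                       rng_seed = 4), oof = oof)
  g5 <- ga_optimize(d, pool, ga_config(population_size = 6, generations = 5,
                                       rng_seed = 4), oof = oof)
  expect_equal(nrow(g0$history), 1)
  expect_gte(g5$best_fitness, g0$best_fitness)
  expect_true(all(diff(g5$history$best_ever) >= 0))
})

test_that("GA runs are reproducible under a fixed seed", {
  d <- scenario_generate(scenario_config(n_majority = 60, n_minority = 30,
                                         rng_seed = 13))
  pool <- cheap_test_pool()
  cfg <- ga_config(population_size = 8, generations = 4, rng_seed = 21)
  r1 <- ga_optimize(d, pool, cfg, cv_folds = 3)
  r2 <- ga_optimize(d, pool, cfg, cv_folds = 3)
  expect_identical(r1$best_chromosome, r2$best_chromosome)
  expect_identical(r1$history, r2$history)
})
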