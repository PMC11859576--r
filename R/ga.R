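## Genetic algorithm over classifier-subset chromosomes: length-10
## bitstrings, roulette-wheel selection with fitness-proportional
## probabilities, multi-point crossover, independent bit-flip mutation,
## and elitism. Fitness is the cross-validated AUC of the stacked model a
## chromosome encodes (accuracy available as an alternative).

#' Genetic-algorithm configuration
#'
#' @param population_size individuals per generation (>= 2; default 20).
#' @param generations number of evolution rounds (default 15).
#' @param crossover_points number of cut points for crossover (default 2;
#'   must be below the chromosome length of 10).
#' @param crossover_rate probability a selected pair is recombined
#'   (default 0.8).
#' @param mutation_rate per-bit flip probability (default 0.05).
#' @param elitism number of best individuals copied unchanged into the
#'   next generation (default 1).
#' @param fitness_metric `"auc"` (default) or `"accuracy"`.
#' @param rng_seed integer seed for the whole run.
#' @return object of class `imb_ga_config`.
#' @export
ga_config <- function(population_size = 20L, generations = 15L,
                      crossover_points = 2L, crossover_rate = 0.8,
                      mutation_rate = 0.05, elitism = 1L,
                      fitness_metric = c("auc", "accuracy"),
                      rng_seed = NULL) {
  fitness_metric <- match.arg(fitness_metric)
  stopifnot(population_size >= 2L, generations >= 0L,
            crossover_points >= 1L, crossover_points < 10L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism >= 0L, elitism < population_size)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_points = as.integer(crossover_points),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 fitness_metric = fitness_metric,
                 rng_seed = rng_seed),
            class = "imb_ga_config")
}

# An all-zero chromosome encodes an empty ensemble; repair by switching
# one uniformly random bit on (consumes the current RNG stream).
repair_chromosome <- function(bits) {
  if (sum(bits) == 0L) bits[sample.int(length(bits), 1L)] <- 1L
  bits
}

#' Roulette-wheel selection
#'
#' Fitness-proportional sampling with replacement: individual `i` is
#' drawn with probability `fit_i / sum(fit)`. Implemented by the
#' cumulative-probability search: draw a uniform value, walk the
#' accumulated selection probabilities, and take the first individual
#' whose accumulated probability exceeds the draw. All-zero fitness
#' degrades to uniform selection with a warning.
#'
#' @param population list of chromosomes (0/1 integer vectors).
#' @param fitness_values non-negative numeric vector, one per individual.
#' @param n_select number of draws.
#' @param seed optional integer seed.
#' @return list of `n_select` chromosomes (possibly repeated).
#' @export
roulette_select <- function(population, fitness_values, n_select,
                            seed = NULL) {
  stopifnot(length(population) == length(fitness_values),
            all(fitness_values >= 0))
  if (n_select == 0L) return(list())
  if (sum(fitness_values) == 0) {
    warning("all fitness values are zero; selecting uniformly",
            call. = FALSE)
    fitness_values <- rep(1, length(fitness_values))
  }
  cum <- cumsum(fitness_values / sum(fitness_values))
  with_seed(seed, {
    u <- stats::runif(n_select)
    idx <- findInterval(u, cum) + 1L  # first i with cum[i] > u
    population[idx]
  })
}

#' Multi-point crossover of two chromosomes
#'
#' Cuts both parents at the same sorted positions and swaps alternating
#' gene blocks, producing two children that conserve the parents'
#' per-position bit multiset.
#'
#' @param parent_a,parent_b 0/1 integer vectors of equal length.
#' @param crossover_points number of cut points (must be below the
#'   chromosome length); ignored when `cuts` is given.
#' @param cuts optional explicit cut positions (subset of
#'   `1:(length-1)`); a cut at position `c` separates genes `1..c` from
#'   `c+1..`.
#' @param seed optional integer seed for sampling cut positions.
#' @return list with elements `child_a`, `child_b`.
#' @export
multipoint_crossover <- function(parent_a, parent_b, crossover_points = 2L,
                                 cuts = NULL, seed = NULL) {
  L <- length(parent_a)
  stopifnot(length(parent_b) == L)
  if (is.null(cuts)) {
    if (crossover_points >= L) {
      stop("crossover_points must be below the chromosome length (", L, ")",
           call. = FALSE)
    }
    cuts <- with_seed(seed, sort(sample.int(L - 1L, crossover_points)))
  } else {
    cuts <- sort(unique(as.integer(cuts)))
    stopifnot(all(cuts >= 1L), all(cuts < L))
  }
  # block index per position; odd blocks stay, even blocks swap
  block <- findInterval(seq_len(L), cuts + 1L) + 1L
  swap <- block %% 2L == 0L
  child_a <- parent_a; child_b <- parent_b
  child_a[swap] <- parent_b[swap]
  child_b[swap] <- parent_a[swap]
  list(child_a = child_a, child_b = child_b)
}

#' Multi-point mutation of a chromosome
#'
#' Flips each bit independently with probability `mutation_rate`; an
#' all-zero result is repaired by switching one random bit on so the
#' chromosome still encodes a non-empty ensemble.
#'
#' @param chromosome 0/1 integer vector.
#' @param mutation_rate per-bit flip probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return mutated chromosome.
#' @export
multipoint_mutation <- function(chromosome, mutation_rate, seed = NULL) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  with_seed(seed, {
    flip <- stats::runif(length(chromosome)) < mutation_rate
    out <- ifelse(flip, 1L - chromosome, chromosome)
    repair_chromosome(as.integer(out))
  })
}

#' GA search for the best first-layer classifier subset
#'
#' Evolves a population of length-10 bitstrings over the classifier
#' pool. Each generation: every chromosome's fitness is the
#' cross-validated AUC of its stacked model (computed from the
#' precomputed out-of-fold matrix, so only the meta-learner is refit per
#' chromosome); the best `elitism` individuals survive unchanged; the
#' rest of the next generation comes from roulette selection, multi-point
#' crossover and bit-flip mutation. Returns the best chromosome ever seen
#' and a per-generation fitness history whose running best is
#' non-decreasing.
#'
#' @param dataset an [imb_dataset].
#' @param pool an [classifier_pool()].
#' @param config an [ga_config()].
#' @param cv_folds stratified folds for the out-of-fold fitness
#'   (default 5).
#' @param oof optional precomputed [pool_oof_matrix()] (all 10 members)
#'   to reuse across calls.
#' @param groups optional fold-grouping vector (see [stratified_folds()]).
#' @param eval_mask optional logical row mask for fitness evaluation
#'   (see [stack_cv_auc()]).
#' @return object of class `imb_ga_result`: list with
#'   `best_chromosome`, `best_fitness`, `history` (data frame:
#'   `generation`, `best`, `mean`, `best_ever`), `evaluations` (distinct
#'   chromosomes scored), `oof` (the matrix used).
#' @export
ga_optimize <- function(dataset, pool = default_pool(),
                        config = ga_config(), cv_folds = 5L, oof = NULL,
                        groups = NULL, eval_mask = NULL) {
  stopifnot(inherits(config, "imb_ga_config"))
  if (is.null(oof)) {
    oof <- pool_oof_matrix(dataset, pool, cv_folds,
                           seed = derive_seed(config$rng_seed, 7),
                           groups = groups)
  }
  L <- ncol(oof$oof)
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(bits) {
    key <- paste(bits, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- stack_cv_auc(oof$oof, oof$y, bits, oof$folds,
                        metric = config$fitness_metric,
                        eval_mask = eval_mask)
    cache[[key]] <- val
    val
  }

  with_seed(config$rng_seed, {
    pop <- lapply(seq_len(config$population_size), function(i) {
      repair_chromosome(as.integer(stats::runif(L) < 0.5))
    })
    best_bits <- NULL
    best_fit <- -Inf
    hist <- vector("list", config$generations + 1L)
    for (g in 0:config$generations) {
      fits <- vapply(pop, fitness_of, numeric(1))
      gen_best <- max(fits)
      if (gen_best > best_fit) {
        best_fit <- gen_best
        best_bits <- pop[[which.max(fits)]]
      }
      hist[[g + 1L]] <- data.frame(generation = g, best = gen_best,
                                   mean = mean(fits), best_ever = best_fit)
      if (g == config$generations) break
      # elitism: carry the current best forward unchanged
      elite <- pop[order(-fits)[seq_len(config$elitism)]]
      n_rest <- config$population_size - config$elitism
      parents <- roulette_select(pop, fits, n_rest)
      children <- list()
      i <- 1L
      while (length(children) < n_rest) {
        pa <- parents[[i]]
        pb <- parents[[min(i + 1L, n_rest)]]
        if (stats::runif(1) < config$crossover_rate) {
          cr <- multipoint_crossover(pa, pb, config$crossover_points)
          pa <- cr$child_a; pb <- cr$child_b
        }
        children <- c(children, list(pa), list(pb))
        i <- i + 2L
        if (i > n_rest) i <- 1L
      }
      children <- children[seq_len(n_rest)]
      children <- lapply(children, multipoint_mutation,
                         mutation_rate = config$mutation_rate)
      pop <- c(elite, children)
    }
    structure(list(best_chromosome = best_bits,
                   best_fitness = best_fit,
                   history = do.call(rbind, hist),
                   evaluations = length(ls(cache)),
                   oof = oof),
              class = "imb_ga_result")
  })
}

#' @export
print.imb_ga_result <- function(x, ...) {
  cat("<imb_ga_result> best chromosome:",
      paste(x$best_chromosome, collapse = ""),
      sprintf(" fitness %.4f (%d chromosomes evaluated)\n",
              x$best_fitness, x$evaluations))
  invisible(x)
}

#' Exhaustive search over all classifier subsets
#'
#' Scores every non-empty chromosome (1023 subsets of a 10-member pool)
#' with the same out-of-fold fitness the GA uses; the reference the GA is
#' benchmarked against.
#'
#' @inheritParams ga_optimize
#' @param metric fitness metric, as in [stack_cv_auc()].
#' @return list with `best_chromosome`, `best_fitness`, `fitness` (named
#'   vector over all subsets, names are bitstrings).
#' @export
exhaustive_stack_search <- function(dataset, pool = default_pool(),
                                    cv_folds = 5L, seed = NULL, oof = NULL,
                                    metric = "auc", groups = NULL,
                                    eval_mask = NULL) {
  if (is.null(oof)) {
    oof <- pool_oof_matrix(dataset, pool, cv_folds,
                           seed = derive_seed(seed, 7), groups = groups)
  }
  L <- ncol(oof$oof)
  n_sub <- 2^L - 1L
  fitness <- numeric(n_sub)
  keys <- character(n_sub)
  for (s in seq_len(n_sub)) {
    bits <- as.integer(intToBits(s)[seq_len(L)])
    fitness[s] <- stack_cv_auc(oof$oof, oof$y, bits, oof$folds,
                               metric = metric, eval_mask = eval_mask)
    keys[s] <- paste(bits, collapse = "")
  }
  names(fitness) <- keys
  best <- which.max(fitness)
  list(best_chromosome = as.integer(intToBits(best)[seq_len(L)]),
       best_fitness = fitness[[best]],
       fitness = fitness)
}

#' Grid search over a classifier's hyperparameters
#'
#' Enumerates the full Cartesian product of the candidate values and
#' scores each combination by stratified cross-validation; the first
#' combination (in enumeration order) attaining the best criterion wins.
#'
#' @param spec a [classifier_spec()].
#' @param dataset an [imb_dataset].
#' @param param_grid named list of candidate value vectors; defaults to
#'   the spec's own `grid`.
#' @param cv_folds stratified folds (default 5).
#' @param criterion `"auc"` (default) or `"accuracy"`.
#' @param seed integer seed (folds + learner RNG).
#' @return list with `best_params` (named list), `best_score`, `results`
#'   (data frame of every combination and its score),
#'   `n_combinations`.
#' @export
grid_search <- function(spec, dataset, param_grid = NULL, cv_folds = 5L,
                        criterion = c("auc", "accuracy"), seed = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(spec, "imb_classifier_spec"))
  if (is.null(param_grid)) param_grid <- spec$grid
  if (length(param_grid) == 0L || any(lengths(param_grid) == 0L)) {
    stop("empty hyperparameter grid for '", spec$id, "'", call. = FALSE)
  }
  combos <- expand.grid(param_grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  folds <- stratified_folds(dataset$y, cv_folds, seed = derive_seed(seed, 1))
  score_one <- function(params) {
    pred <- numeric(length(dataset$y))
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      fit <- fit_classifier(spec, dataset$X[tr, , drop = FALSE],
                            dataset$y[tr], params = params,
                            seed = derive_seed(seed, 200 + f))
      pred[!tr] <- predict_minority_prob(fit,
                                         dataset$X[!tr, , drop = FALSE])
    }
    if (criterion == "auc") auc(dataset$y, pred, 0L)
    else mean((pred >= 0.5) == (dataset$y == 0L))
  }
  scores <- vapply(seq_len(nrow(combos)), function(i) {
    score_one(as.list(combos[i, , drop = FALSE]))
  }, numeric(1))
  best <- which.max(scores)  # first maximum in enumeration order
  results <- cbind(combos, score = scores)
  list(best_params = as.list(combos[best, , drop = FALSE]),
       best_score = scores[best],
       results = results,
       n_combinations = nrow(combos))
}
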