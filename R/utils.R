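# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stage seed from a global seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset * 9973) %% 2147483629)
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each observation to one of `k` folds so that both classes are
#' spread as evenly as possible across folds.
#'
#' @param y binary label vector (0/1).
#' @param k number of folds (>= 2).
#' @param seed optional integer seed controlling the permutation.
#' @param groups optional grouping vector: rows sharing a group id are
#'   always assigned to the same fold. Used to keep interpolation-derived
#'   synthetic samples in the fold of their base sample, so out-of-fold
#'   estimates are not inflated by near-copies straddling the fold
#'   boundary.
#' @return integer vector of fold ids in `1:k`, one per observation.
#' @export
stratified_folds <- function(y, k, seed = NULL, groups = NULL) {
  stopifnot(k >= 2)
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(y))
    reps <- !duplicated(groups)
    gfolds <- stratified_folds(y[reps], k, seed)
    return(gfolds[match(groups, groups[reps])])
  }
  counts <- table(factor(y, levels = c(0, 1)))
  if (min(counts) < k) {
    stop("cannot build ", k, " stratified folds: smallest class has only ",
         min(counts), " samples; use fewer folds", call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Pairwise squared Euclidean distances between rows of A and rows of B.
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}
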