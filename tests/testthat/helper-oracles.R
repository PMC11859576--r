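# Independent oracles and small fixture builders used across tests.
# Everything here is deliberately written as direct enumeration / direct
# summation, separate from the package's own code paths.

# dataset with given class counts and throwaway features
mk_counts_dataset <- function(n0, n1, p = 1, seed = 1) {
  set.seed(seed)
  imb_dataset(matrix(rnorm((n0 + n1) * p), n0 + n1, p),
              rep(c(0L, 1L), c(n0, n1)))
}

# brute-force O(n^2) Tomek-link scan: cross-class pairs that are each
# other's single nearest neighbour, via the full distance matrix
oracle_tomek_links <- function(X, y) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  links <- list()
  for (i in seq_len(nrow(X))) {
    j <- which.min(D[i, ])
    if (y[i] != y[j] && which.min(D[j, ]) == i && i < j) {
      links[[length(links) + 1L]] <- c(i, j)
    }
  }
  links
}

# direct-summation evaluation of the two F-score formulas
oracle_fscore <- function(v, y, improved = FALSE) {
  vp <- v[y == 1]; vn <- v[y == 0]          # n+ = majority, n- = minority
  mu <- sum(v) / length(v)
  mup <- sum(vp) / length(vp)
  mun <- sum(vn) / length(vn)
  num <- (mup - mu)^2 + (mun - mu)^2
  den <- sum((vp - mup)^2) / (length(vp) - 1)
  if (!improved) den <- den + sum((vn - mun)^2) / (length(vn) - 1)
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

# Mann-Whitney pair-counting AUC with half credit for ties
oracle_auc_pairs <- function(y_true, y_score, positive_label = 0) {
  sp <- y_score[y_true == positive_label]
  sn <- y_score[y_true != positive_label]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# does point u lie on the segment between some pair of rows of M?
oracle_on_some_segment <- function(u, M, tol = 1e-9) {
  n <- nrow(M)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- M[i, ]; b <- M[j, ]
      gap <- sqrt(sum((u - a)^2)) + sqrt(sum((u - b)^2)) -
        sqrt(sum((b - a)^2))
      if (abs(gap) <= tol) return(TRUE)
    }
  }
  FALSE
}

# a cheap custom pool for GA tests: `n_signal` members whose scores carry
# the label signal (logistic fits on disjoint feature blocks), the rest
# emitting label-independent deterministic noise
cheap_test_pool <- function(n_signal = 2) {
  mk_signal <- function(k) {
    classifier_spec(
      id = paste0("sig", k),
      fit = function(X, y, params) {
        j <- ((k - 1) %% ncol(X)) + 1
        df <- data.frame(x = X[, j], y = as.numeric(y == 0))
        suppressWarnings(glm(y ~ x, data = df, family = binomial()))
      },
      predict_prob = function(model, X) {
        j <- ((k - 1) %% ncol(X)) + 1
        suppressWarnings(predict(model, data.frame(x = X[, j]),
                                 type = "response"))
      })
  }
  mk_noise <- function(k) {
    classifier_spec(
      id = paste0("noise", k),
      fit = function(X, y, params) NULL,
      predict_prob = function(model, X) {
        # deterministic, row-dependent, label-independent
        (sin(rowSums(X) * 37.1 + k * 11.3) + 1) / 2
      })
  }
  specs <- c(lapply(seq_len(n_signal), mk_signal),
             lapply(seq_len(10 - n_signal), mk_noise))
  classifier_pool(specs)
}
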