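#' Result of a resampling operation
#'
#' Wraps the resampled dataset together with provenance: which output rows
#' were synthesised, which input rows were deleted, and how many cleaning
#' passes ran.
#'
#' @param dataset the resampled [imb_dataset].
#' @param synthetic_mask logical vector over output rows, `TRUE` for rows
#'   created by oversampling.
#' @param deleted_indices integer indices (into the *input* of the
#'   operation) of rows removed by cleaning.
#' @param iterations number of cleaning passes performed (>= 1 for
#'   [dums_clean()]; 0 when no cleaning stage ran).
#' @param synthetic_base for each output row, the input-row index of the
#'   base sample a synthetic row was interpolated from (`NA` for original
#'   rows); lets downstream cross-validation keep a synthetic point in
#'   the same fold as its base.
#' @param row_indices for each output row, its index in the operation's
#'   input (identity for pure oversampling, surviving indices after
#'   cleaning).
#' @return object of class `imb_sampling_result`.
#' @keywords internal
new_sampling_result <- function(dataset, synthetic_mask,
                                deleted_indices = integer(0),
                                iterations = 0L,
                                synthetic_base = NULL,
                                row_indices = NULL) {
  stopifnot(inherits(dataset, "imb_dataset"),
            length(synthetic_mask) == nrow(dataset$X))
  if (is.null(synthetic_base)) {
    synthetic_base <- rep(NA_integer_, nrow(dataset$X))
  }
  if (is.null(row_indices)) row_indices <- seq_len(nrow(dataset$X))
  structure(list(dataset = dataset,
                 synthetic_mask = synthetic_mask,
                 deleted_indices = as.integer(deleted_indices),
                 iterations = as.integer(iterations),
                 synthetic_base = as.integer(synthetic_base),
                 row_indices = as.integer(row_indices)),
            class = "imb_sampling_result")
}

#' Fold-grouping vector from a sampling result
#'
#' Returns one group id per row of the resampled dataset, placing every
#' synthetic sample in the group of the original sample it was
#' interpolated from. Passing this to [stratified_folds()] (via the
#' `groups` arguments of the wrapper, stack and GA functions) keeps
#' near-duplicate interpolants on one side of each fold boundary, so
#' cross-validated AUCs on oversampled data stay honest.
#'
#' @param result an `imb_sampling_result`.
#' @return integer group vector, length `nrow(result$dataset$X)`.
#' @export
sampling_groups <- function(result) {
  stopifnot(inherits(result, "imb_sampling_result"))
  ifelse(is.na(result$synthetic_base), result$row_indices,
         result$synthetic_base)
}

#' @export
print.imb_sampling_result <- function(x, ...) {
  cat("<imb_sampling_result> ", sum(x$synthetic_mask), " synthetic rows, ",
      length(x$deleted_indices), " deleted rows, ",
      x$iterations, " cleaning pass(es)\n", sep = "")
  print(x$dataset)
  invisible(x)
}

#' Minority oversampling by nearest-neighbour interpolation (AMOM)
#'
#' Grows the minority class (label 0) by interpolation: repeatedly pick a
#' minority sample `u_i`, one of its `m` nearest minority neighbours
#' `u_ij` under Euclidean distance, and a scalar `s ~ Uniform(0, 1)`, and
#' add the synthetic point `u_i + s * (u_ij - u_i)`. Every synthetic point
#' therefore lies on the segment between two original minority samples.
#' Oversampling continues until the minority count reaches
#' `ceiling(target_ratio * majority count)`.
#'
#' Distances are meaningful only on a common feature scale; normalize
#' first (see [minmax_normalize()]).
#'
#' @param dataset an [imb_dataset].
#' @param m number of nearest minority neighbours to draw from (default 5).
#'   Must be smaller than the minority class size.
#' @param target_ratio desired minority/majority count ratio after
#'   oversampling, in (0, 1]; default 1 (full balance).
#' @param seed optional integer seed; fixed seed gives identical output.
#' @return an `imb_sampling_result`; synthetic rows are appended after the
#'   original rows, labelled 0 and tagged `"synthetic_amom"`.
#' @examples
#' d <- scenario_generate(scenario_config(n_majority = 60, n_minority = 12,
#'                                        rng_seed = 1))
#' res <- amom_oversample(d, m = 5, seed = 1)
#' table(res$dataset$y)
#' @export
amom_oversample <- function(dataset, m = 5L, target_ratio = 1.0,
                            seed = NULL) {
  stopifnot(inherits(dataset, "imb_dataset"))
  check_both_classes(dataset, "oversampling")
  if (target_ratio <= 0 || target_ratio > 1) {
    stop("target_ratio must be in (0, 1]", call. = FALSE)
  }
  min_idx <- which(dataset$y == 0L)
  n_min <- length(min_idx)
  n_maj <- sum(dataset$y == 1L)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (n_min < m + 1L) {
    stop("minority class has ", n_min, " samples but m = ", m,
         " neighbours were requested; use m <= ", n_min - 1L, call. = FALSE)
  }
  n_target <- ceiling(target_ratio * n_maj)
  n_new <- n_target - n_min
  if (n_new <= 0L) {
    warning("minority count (", n_min, ") already meets the target (",
            n_target, "); no samples generated", call. = FALSE)
    return(new_sampling_result(dataset, rep(FALSE, nrow(dataset$X))))
  }

  Xmin <- dataset$X[min_idx, , drop = FALSE]
  d2 <- cross_dist2(Xmin, Xmin)
  diag(d2) <- Inf
  # m nearest minority neighbours per minority sample; ties -> lowest index
  nn <- do.call(rbind, lapply(seq_len(n_min), function(i) {
    order(d2[i, ])[seq_len(m)]
  }))

  synth <- with_seed(seed, {
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- sample.int(m, n_new, replace = TRUE)
    s <- stats::runif(n_new)
    ui <- Xmin[base, , drop = FALSE]
    uj <- Xmin[nn[cbind(base, pick)], , drop = FALSE]
    pts <- ui + s * (uj - ui)
    attr(pts, "base_index") <- min_idx[base]
    pts
  })

  X_out <- rbind(dataset$X, synth)
  y_out <- c(dataset$y, rep(0L, n_new))
  prov <- c(dataset$provenance, rep("synthetic_amom", n_new))
  out <- imb_dataset(X_out, y_out, dataset$feature_names, prov)
  new_sampling_result(out, c(rep(FALSE, nrow(dataset$X)), rep(TRUE, n_new)),
                      synthetic_base = c(rep(NA_integer_, nrow(dataset$X)),
                                         attr(synth, "base_index")))
}

# Index of each row's single nearest neighbour over the whole dataset
# (self excluded); distance ties broken by lowest row index.
nearest_neighbour_all <- function(X) {
  d2 <- cross_dist2(X, X)
  diag(d2) <- Inf
  apply(d2, 1, which.min)  # which.min takes the first minimum: lowest index
}

# Brute-force Tomek-link finder: pairs (i, j), i < j, of opposite class
# that are each other's single nearest neighbour.
find_tomek_links <- function(X, y) {
  nn <- nearest_neighbour_all(X)
  i <- seq_along(y)
  mutual <- nn[nn[i]] == i & y[nn[i]] != y[i]
  pairs <- cbind(i[mutual], nn[i][mutual])
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  pairs
}

#' Boundary cleaning by iterated Tomek-link removal (DUMS)
#'
#' Finds cross-class mutual-nearest-neighbour pairs (Tomek links) —
#' opposite-class samples sitting one step from each other with no closer
#' neighbour — and deletes one or both members, repeating until no link
#' remains. Such pairs mark borderline or noisy points, including noise
#' introduced by interpolation oversampling; removing them sharpens the
#' class boundary.
#'
#' @param dataset an [imb_dataset].
#' @param policy which member of each link to delete: `"majority"`
#'   (default; preserves scarce minority information) or `"both"`.
#' @param max_iter safety cap on cleaning passes (default 100).
#' @return an `imb_sampling_result`; `deleted_indices` refer to rows of
#'   the input `dataset`, `iterations` counts passes (the final pass finds
#'   nothing). Deletion stops, with a warning, before a class would be
#'   emptied.
#' @export
dums_clean <- function(dataset, policy = c("majority", "both"),
                       max_iter = 100L) {
  stopifnot(inherits(dataset, "imb_dataset"))
  policy <- match.arg(policy)
  check_both_classes(dataset, "boundary cleaning")
  X <- dataset$X
  if (nrow(unique(X)) == 1L) {
    stop("all samples identical: nearest-neighbour cleaning is undefined",
         call. = FALSE)
  }
  keep <- seq_len(nrow(X))  # indices into the original dataset
  deleted <- integer(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    y_cur <- dataset$y[keep]
    links <- find_tomek_links(X[keep, , drop = FALSE], y_cur)
    if (nrow(links) == 0L || iter > max_iter) break
    if (policy == "majority") {
      drop_local <- unique(ifelse(y_cur[links[, 1]] == 1L,
                                  links[, 1], links[, 2]))
    } else {
      drop_local <- unique(as.vector(links))
    }
    # never empty a class
    for (cls in c(0L, 1L)) {
      cls_local <- which(y_cur == cls)
      if (all(cls_local %in% drop_local)) {
        warning("cleaning would empty class ", cls,
                "; retaining its remaining samples", call. = FALSE)
        drop_local <- setdiff(drop_local, cls_local)
      }
    }
    if (length(drop_local) == 0L) break
    deleted <- c(deleted, keep[drop_local])
    keep <- keep[-drop_local]
  }
  out <- imb_dataset(X[keep, , drop = FALSE], dataset$y[keep],
                     dataset$feature_names, dataset$provenance[keep])
  new_sampling_result(out,
                      synthetic_mask = dataset$provenance[keep] == "synthetic_amom",
                      deleted_indices = sort(deleted),
                      iterations = iter,
                      row_indices = keep)
}

#' Hybrid resampling: oversample then clean (AMOM-DUMS)
#'
#' The composed sampler: [amom_oversample()] grows the minority class by
#' interpolation, then [dums_clean()] removes the boundary noise the
#' interpolation can introduce, scanning originals and synthetic points
#' alike. The result carries both masks: which surviving rows are
#' synthetic and which input-union rows were deleted.
#'
#' @inheritParams amom_oversample
#' @inheritParams dums_clean
#' @return an `imb_sampling_result`; `deleted_indices` index the
#'   oversampled (original + synthetic) row union.
#' @examples
#' d <- scenario_generate(scenario_config(n_majority = 100, n_minority = 10,
#'                                        class_separation = 1, rng_seed = 7))
#' res <- amom_dums(d, seed = 7)
#' compute_ur(res$dataset)  # close to 1 after balancing
#' @export
amom_dums <- function(dataset, m = 5L, target_ratio = 1.0, seed = NULL,
                      policy = c("majority", "both")) {
  over <- amom_oversample(dataset, m = m, target_ratio = target_ratio,
                          seed = seed)
  cleaned <- dums_clean(over$dataset, policy = policy)
  # compose provenance: row/base indices refer to the oversampled union
  cleaned$synthetic_base <- over$synthetic_base[cleaned$row_indices]
  cleaned
}
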