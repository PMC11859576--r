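#' Imbalanced binary-classification dataset
#'
#' The container passed between every stage of the pipeline: a numeric
#' feature matrix, a binary label vector, feature names, and an optional
#' per-row provenance tag recording which rows were synthesised by
#' oversampling.
#'
#' The label convention is fixed package-wide: `0` is the minority class of
#' interest (the rare clinical outcome, e.g. the hypertensive pregnancy),
#' `1` is the majority class. Every reader and generator validates it.
#'
#' @param X numeric matrix or data frame, one row per sample, one column
#'   per feature.
#' @param y vector coercible to integer, values in `{0, 1}`; `0` codes the
#'   minority class.
#' @param feature_names character vector of column names; defaults to
#'   `colnames(X)` or `f1..fp`.
#' @param provenance optional character vector per row, values in
#'   `c("original", "synthetic_amom")`; defaults to all `"original"`.
#' @return an object of class `imb_dataset` with elements `X`, `y`,
#'   `feature_names`, `provenance`.
#' @examples
#' d <- imb_dataset(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
#' compute_ur(d)
#' @export
imb_dataset <- function(X, y, feature_names = NULL, provenance = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) != length(y)) {
    stop("X has ", nrow(X), " rows but y has length ", length(y),
         call. = FALSE)
  }
  if (!all(y %in% c(0L, 1L))) {
    bad <- unique(y[!y %in% c(0L, 1L)])
    stop("labels must be 0 (minority) or 1 (majority); found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop("non-finite feature value at row ", bad[1], ", column ", bad[2],
         call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  }
  if (length(feature_names) != ncol(X)) {
    stop("feature_names length (", length(feature_names),
         ") does not match column count (", ncol(X), ")", call. = FALSE)
  }
  colnames(X) <- feature_names
  if (is.null(provenance)) provenance <- rep("original", nrow(X))
  stopifnot(length(provenance) == nrow(X),
            all(provenance %in% c("original", "synthetic_amom")))
  structure(list(X = X, y = y, feature_names = feature_names,
                 provenance = provenance),
            class = "imb_dataset")
}

#' @export
print.imb_dataset <- function(x, ...) {
  n0 <- sum(x$y == 0L); n1 <- sum(x$y == 1L)
  cat("<imb_dataset> ", nrow(x$X), " samples x ", ncol(x$X), " features\n",
      "  minority (0): ", n0, "   majority (1): ", n1, sep = "")
  if (n0 > 0 && n1 > 0) cat("   UR: ", format(round(compute_ur(x), 3)), sep = "")
  n_syn <- sum(x$provenance == "synthetic_amom")
  if (n_syn > 0) cat("\n  synthetic rows: ", n_syn, sep = "")
  cat("\n")
  invisible(x)
}

check_both_classes <- function(dataset, what = "this operation") {
  if (sum(dataset$y == 0L) == 0L) {
    stop("minority class (label 0) is empty; ", what,
         " requires both classes", call. = FALSE)
  }
  if (sum(dataset$y == 1L) == 0L) {
    stop("majority class (label 1) is empty; ", what,
         " requires both classes", call. = FALSE)
  }
  invisible(TRUE)
}

#' Unbalanced ratio (UR)
#'
#' The degree of class imbalance, quantified as the majority-class count
#' divided by the minority-class count. Values above 1 mean the majority
#' outnumbers the minority; a balanced dataset has UR 1. Display contexts
#' round to 3 decimals; the returned value is full precision.
#'
#' @param dataset an [imb_dataset].
#' @return a single numeric, `sum(y == 1) / sum(y == 0)`.
#' @examples
#' d <- imb_dataset(matrix(0, 2087, 1), rep(c(0, 1), c(392, 1695)))
#' round(compute_ur(d), 3)  # 4.324
#' @export
compute_ur <- function(dataset) {
  stopifnot(inherits(dataset, "imb_dataset"))
  check_both_classes(dataset, "the unbalanced ratio")
  sum(dataset$y == 1L) / sum(dataset$y == 0L)
}

#' Min-max normalization to [0, 1]
#'
#' Rescales each feature by its own range, `(v - min) / (max - min)`, so
#' all features live on a common unitless `[0, 1]` scale before distance
#' computations and model fitting. Constant features (zero range) map to 0
#' with a warning. Fitted minima/maxima are returned so the identical
#' transform can be reapplied to held-out data.
#'
#' @param dataset an [imb_dataset].
#' @param params optional `imb_norm_params` from an earlier call; when
#'   supplied, those minima/maxima are applied instead of refitting (values
#'   outside the training range are clipped to `[0, 1]`).
#' @return list with elements `dataset` (normalized copy) and `params`
#'   (class `imb_norm_params`: per-feature `min` and `max`).
#' @examples
#' d <- imb_dataset(matrix(c(2, 4, 6), 3, 1), c(0, 1, 1))
#' minmax_normalize(d)$dataset$X  # 0, 0.5, 1
#' @export
minmax_normalize <- function(dataset, params = NULL) {
  stopifnot(inherits(dataset, "imb_dataset"))
  X <- dataset$X
  if (is.null(params)) {
    fmin <- apply(X, 2, min)
    fmax <- apply(X, 2, max)
    params <- structure(list(min = fmin, max = fmax,
                             feature_names = dataset$feature_names),
                        class = "imb_norm_params")
    if (any(fmax == fmin)) {
      warning("constant feature(s) mapped to 0: ",
              paste(dataset$feature_names[fmax == fmin], collapse = ", "),
              call. = FALSE)
    }
  } else {
    stopifnot(inherits(params, "imb_norm_params"),
              identical(params$feature_names, dataset$feature_names))
    fmin <- params$min
    fmax <- params$max
  }
  rng <- fmax - fmin
  rng[rng == 0] <- 1  # constant features map to 0
  Xn <- sweep(sweep(X, 2, fmin, "-"), 2, rng, "/")
  Xn[Xn < 0] <- 0
  Xn[Xn > 1] <- 1
  out <- imb_dataset(Xn, dataset$y, dataset$feature_names, dataset$provenance)
  list(dataset = out, params = params)
}

#' Body mass index
#'
#' Weight divided by height squared, the standard anthropometric index
#' used as a derived covariate in perinatal risk models.
#'
#' @param weight_kg body weight in kilograms (> 0).
#' @param height_m height in metres (> 0).
#' @return BMI in kg/m^2; vectorized.
#' @examples
#' derive_bmi(60, 1.6)  # 23.4375
#' @export
derive_bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("weight_kg must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(height_m)) || any(height_m <= 0)) {
    stop("height_m must be positive and finite", call. = FALSE)
  }
  weight_kg / height_m^2
}

#' Season code from calendar month
#'
#' Ordinal season encoding used for date-derived covariates:
#' spring (Mar-May) = 1, summer (Jun-Aug) = 2, autumn (Sep-Nov) = 3,
#' winter (Dec-Feb) = 4.
#'
#' @param month integer month 1-12; vectorized.
#' @return integer season code in 1-4.
#' @export
derive_season <- function(month) {
  month <- as.integer(month)
  if (any(is.na(month)) || any(month < 1L | month > 12L)) {
    stop("month must be an integer in 1..12", call. = FALSE)
  }
  c(4L, 4L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L)[month]
}

#' Read a dataset from delimited text
#'
#' Reads a CSV/TSV file with a header row into an [imb_dataset]. The label
#' column must be binary with `0` coding the minority class. Missing-value
#' handling: feature columns with more than `na_col_threshold` missing
#' entries are dropped, then any remaining rows containing missing values
#' are dropped; both actions are reported via `message()`.
#'
#' @param path file path.
#' @param label_column name of the label column (default `"label"`).
#' @param sep field separator; `NULL` (default) infers `"\t"` for
#'   `.tsv`/`.txt`, `","` otherwise.
#' @param na_col_threshold drop feature columns whose missing fraction
#'   exceeds this (default 0.2).
#' @return an [imb_dataset].
#' @export
read_dataset <- function(path, label_column = "label", sep = NULL,
                         na_col_threshold = 0.2) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found; columns are: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  y <- df[[label_column]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("label column '", label_column,
         "' must contain only 0 (minority) and 1 (majority)", call. = FALSE)
  }
  feat <- df[setdiff(names(df), label_column)]
  if (!all(vapply(feat, is.numeric, logical(1)))) {
    bad <- names(feat)[!vapply(feat, is.numeric, logical(1))]
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  na_frac <- vapply(feat, function(v) mean(is.na(v)), numeric(1))
  if (any(na_frac > na_col_threshold)) {
    dropped <- names(feat)[na_frac > na_col_threshold]
    message("dropping ", length(dropped), " column(s) with > ",
            100 * na_col_threshold, "% missing: ",
            paste(dropped, collapse = ", "))
    feat <- feat[na_frac <= na_col_threshold]
  }
  keep <- stats::complete.cases(feat)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " row(s) with missing values")
    feat <- feat[keep, , drop = FALSE]
    y <- y[keep]
  }
  imb_dataset(as.matrix(feat), y)
}

#' Write a dataset to delimited text
#'
#' Inverse of [read_dataset()]: features plus a label column, with full
#' float precision so a write-read round trip reproduces the matrix.
#'
#' @param dataset an [imb_dataset].
#' @param path output path; `.tsv` extension selects tab separation.
#' @param label_column label column name (default `"label"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, label_column = "label") {
  stopifnot(inherits(dataset, "imb_dataset"))
  df <- as.data.frame(dataset$X)
  df[[label_column]] <- dataset$y
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
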