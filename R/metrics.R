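#' ROC curve by score thresholding
#'
#' Sweeps the decision threshold over the distinct score values and
#' records (false positive rate, true positive rate) pairs, from (0, 0)
#' to (1, 1). Tied scores enter as a single threshold step, which makes
#' the trapezoidal area under this curve equal to the Mann-Whitney
#' U-statistic probability with the midpoint (half-credit) tie
#' convention.
#'
#' @param y_true binary labels.
#' @param y_score numeric scores; larger means more likely positive.
#' @param positive_label which label is the positive class (default 0,
#'   the minority).
#' @return data frame with columns `threshold`, `fpr`, `tpr`; the first
#'   row is the `(0, 0)` endpoint with threshold `Inf`.
#' @export
roc_curve <- function(y_true, y_score, positive_label = 0L) {
  stopifnot(length(y_true) == length(y_score))
  pos <- y_true == positive_label
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC undefined: y_true contains a single class", call. = FALSE)
  }
  ord <- order(y_score, decreasing = TRUE)
  sc <- y_score[ord]; p <- pos[ord]
  # collapse tied scores into single steps
  last_of_tie <- c(sc[-length(sc)] != sc[-1], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  data.frame(threshold = c(Inf, sc[last_of_tie]),
             fpr = c(0, fp / n_neg),
             tpr = c(0, tp / n_pos))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of [roc_curve()]; equal to the probability
#' that a random positive outscores a random negative, with ties counted
#' half.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0, 0, 1, 1), c(0.9, 0.8, 0.3, 0.1), positive_label = 0)  # 1
#' @export
auc <- function(y_true, y_score, positive_label = 0L) {
  r <- roc_curve(y_true, y_score, positive_label)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

#' Threshold and threshold-free evaluation metrics
#'
#' Computes accuracy, precision, recall and F-score at a decision
#' threshold on the score, plus the threshold-free ROC curve and AUC.
#' The positive class defaults to the minority label 0, so recall is the
#' fraction of true rare-outcome cases detected; the recall of the other
#' class is also reported since either convention appears in practice.
#'
#' @param y_true binary labels (0/1).
#' @param y_score scores for the positive class, typically probabilities.
#' @param threshold decision cutoff: predict positive when
#'   `y_score >= threshold` (default 0.5).
#' @param positive_label 0 (default, minority) or 1.
#' @return object of class `imb_eval_report`: list with `accuracy`,
#'   `precision`, `recall`, `recall_other`, `f_score`, `auc`,
#'   `roc_points`, `threshold`, `positive_class_label`, and the confusion
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
classification_report <- function(y_true, y_score, threshold = 0.5,
                                  positive_label = 0L) {
  stopifnot(length(y_true) == length(y_score),
            positive_label %in% c(0L, 1L),
            all(y_true %in% c(0L, 1L)))
  pos <- y_true == positive_label
  pred_pos <- y_score >= threshold
  tp <- sum(pred_pos & pos);  fp <- sum(pred_pos & !pos)
  fn <- sum(!pred_pos & pos); tn <- sum(!pred_pos & !pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  recall_other <- if (tn + fp > 0) tn / (tn + fp) else 0
  f_score <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(accuracy = (tp + tn) / length(y_true),
                 precision = precision,
                 recall = recall,
                 recall_other = recall_other,
                 f_score = f_score,
                 auc = auc(y_true, y_score, positive_label),
                 roc_points = roc_curve(y_true, y_score, positive_label),
                 threshold = threshold,
                 positive_class_label = as.integer(positive_label),
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "imb_eval_report")
}

#' @export
print.imb_eval_report <- function(x, ...) {
  cat("<imb_eval_report> positive class:", x$positive_class_label,
      " threshold:", x$threshold, "\n")
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f  F %.3f  AUC %.3f\n",
              x$accuracy, x$precision, x$recall, x$f_score, x$auc))
  invisible(x)
}

#' Write an evaluation report as JSON (and optional ROC CSV)
#'
#' @param report an `imb_eval_report`.
#' @param path JSON output path.
#' @param roc_csv optional path for a `fpr,tpr,threshold` CSV of the ROC
#'   points.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, roc_csv = NULL) {
  stopifnot(inherits(report, "imb_eval_report"))
  out <- report[c("accuracy", "precision", "recall", "recall_other",
                  "f_score", "auc", "threshold", "positive_class_label",
                  "tp", "fp", "tn", "fn")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc_csv)) {
    utils::write.csv(report$roc_points[c("fpr", "tpr", "threshold")],
                     roc_csv, row.names = FALSE)
  }
  invisible(path)
}
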