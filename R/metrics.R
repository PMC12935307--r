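#' Binarize a probability track
#'
#' @param p Numeric vector of probabilities.
#' @param threshold Decision threshold; a probability exactly equal to the
#'   threshold is classified positive.
#' @return Integer vector of 0/1 labels.
#' @export
binarize <- function(p, threshold = 0.5) {
  as.integer(p >= threshold)
}

#' Confusion counts for binary predictions
#'
#' @param truth Binary ground-truth labels.
#' @param pred Binary predicted labels.
#' @return Object of class `confusion_counts`: named integer vector with
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  if (length(truth) != length(pred)) {
    stop("truth and prediction tracks differ in length")
  }
  structure(c(tp = sum(truth == 1L & pred == 1L),
              fp = sum(truth == 0L & pred == 1L),
              tn = sum(truth == 0L & pred == 0L),
              fn = sum(truth == 1L & pred == 0L)),
            class = "confusion_counts")
}

.as_counts <- function(x, pred) {
  if (inherits(x, "confusion_counts")) return(x)
  if (is.null(pred)) stop("supply either confusion counts or truth and prediction vectors")
  confusion_counts(x, pred)
}

#' F1 score
#'
#' Harmonic mean of precision and recall. A degenerate denominator (no
#' predicted and no actual positives) returns 0 with a warning.
#'
#' @param x Either a `confusion_counts` object or a binary truth vector.
#' @param pred Binary prediction vector when `x` is a truth vector.
#' @return Scalar in `[0, 1]`.
#' @export
f1_score <- function(x, pred = NULL) {
  cc <- .as_counts(x, pred)
  denom <- 2 * cc[["tp"]] + cc[["fp"]] + cc[["fn"]]
  if (denom == 0) {
    warning("F1 undefined (no positive labels or predictions); returning 0")
    return(0)
  }
  2 * cc[["tp"]] / denom
}

#' Matthews correlation coefficient
#'
#' Balanced binary-classification statistic in `[-1, 1]`. A zero denominator
#' (any confusion margin empty) returns 0 with a warning.
#'
#' @inheritParams f1_score
#' @return Scalar in `[-1, 1]`.
#' @export
mcc_score <- function(x, pred = NULL) {
  cc <- .as_counts(x, pred)
  tp <- as.numeric(cc[["tp"]]); fp <- as.numeric(cc[["fp"]])
  tn <- as.numeric(cc[["tn"]]); fn <- as.numeric(cc[["fn"]])
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) {
    warning("MCC undefined (degenerate confusion margin); returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / denom
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability (trapezoid rule on
#' the ROC curve), with the standard tie correction.
#'
#' @param labels Binary ground-truth labels with both classes present.
#' @param scores Numeric prediction scores.
#' @return Scalar in `[0, 1]`, or `NA` with a warning for single-class input.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("ROC AUC undefined for single-class input")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Precision-recall step summation (average-precision style): thresholds
#' sweep the distinct scores in decreasing order and each recall increment
#' is weighted by the precision at that threshold. Trapezoidal
#' interpolation, which is optimistic in PR space, is deliberately avoided.
#'
#' @inheritParams roc_auc
#' @return Scalar in `[0, 1]`, or `NA` with a warning for single-class input.
#' @export
pr_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || n_pos == length(labels)) {
    warning("PR AUC undefined for single-class input")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(1L - lab)
  # evaluate only at the last index of each tied score block
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Per-protein evaluation of probability tracks
#'
#' Computes PR AUC, ROC AUC, F1 and MCC per complex and then averages each
#' metric unweighted across complexes, the convention used for paratope
#' benchmarks. Complexes with a single label class are excluded from the AUC
#' averages and counted in the report.
#'
#' @param tracks A list; each element is a list/data frame with components
#'   `labels` (binary) and `probabilities` (numeric, same length).
#' @param threshold Binarization threshold for F1 and MCC.
#' @return Object of class `metrics_report`: `per_complex` data frame,
#'   `means` named vector, `threshold`, `n_excluded_auc`.
#' @examples
#' tr <- list(list(labels = c(1, 0, 1, 0), probabilities = c(.9, .2, .6, .4)),
#'            list(labels = c(0, 0, 1), probabilities = c(.1, .7, .8)))
#' evaluate_dataset(tr)$means
#' @export
evaluate_dataset <- function(tracks, threshold = 0.5) {
  if (length(tracks) == 0L) stop("no complexes to evaluate")
  rows <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    y <- as.integer(tr$labels)
    p <- as.numeric(tr$probabilities)
    single <- length(unique(y)) < 2L
    pr <- if (single) NA_real_ else pr_auc(y, p)
    roc <- if (single) NA_real_ else roc_auc(y, p)
    b <- binarize(p, threshold)
    data.frame(complex = i, pr_auc = pr, roc_auc = roc,
               f1 = suppressWarnings(f1_score(y, b)),
               mcc = suppressWarnings(mcc_score(y, b)))
  })
  per <- do.call(rbind, rows)
  means <- c(pr_auc = mean(per$pr_auc, na.rm = TRUE),
             roc_auc = mean(per$roc_auc, na.rm = TRUE),
             f1 = mean(per$f1), mcc = mean(per$mcc))
  structure(list(per_complex = per, means = means, threshold = threshold,
                 n_excluded_auc = sum(is.na(per$pr_auc))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("per-protein metrics over", nrow(x$per_complex), "complex(es)",
      sprintf("(threshold %.2f)\n", x$threshold))
  print(round(x$means, 4))
  if (x$n_excluded_auc > 0) {
    cat(x$n_excluded_auc, "single-class complex(es) excluded from AUC averages\n")
  }
  invisible(x)
}
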