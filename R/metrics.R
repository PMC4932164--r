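#' Confusion counts with AD as the positive class
#'
#' @param truth,pred Vectors of true and predicted class labels.
#' @param positive Label of the positive class (default `"AD"`).
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(truth, pred, positive = "AD") {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred), length(truth) >= 1L)
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fn <- sum(truth == positive & pred != positive)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, positive = positive),
            class = "confusion_counts")
}

#' Metric panel from confusion counts
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive value, the false discovery rate `1 - PPV` and false
#' omission rate `1 - NPV` (confusion-matrix complements, not
#' multiple-testing quantities), and accuracy. A ratio with a zero
#' denominator is `NA` and is excluded from downstream averages.
#'
#' @param counts A [confusion_counts()] or a list with `tp`, `fp`, `tn`, `fn`.
#' @return Named numeric vector of class `metric_set` with entries
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `fdr`, `for_rate`,
#'   `accuracy`, `auc` (the last `NA` here; filled by score-based callers).
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0), tp + fp + tn + fn >= 1)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  ppv <- div(tp, tp + fp); npv <- div(tn, tn + fn)
  out <- c(sensitivity = div(tp, tp + fn),
           specificity = div(tn, tn + fp),
           ppv = ppv, npv = npv,
           fdr = if (is.na(ppv)) NA_real_ else 1 - ppv,
           for_rate = if (is.na(npv)) NA_real_ else 1 - npv,
           accuracy = (tp + tn) / (tp + fp + tn + fn),
           auc = NA_real_)
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  v <- unclass(x)
  cat(paste(sprintf("%s=%s", names(v),
                    ifelse(is.na(v), "NA", formatC(v, digits = digits, format = "f"))),
            collapse = "  "), "\n")
  invisible(x)
}

#' ROC curve and AUC from decision scores
#'
#' The AUC is the Mann-Whitney rank statistic: the probability that a random
#' positive sample scores above a random negative one, with tied pairs
#' contributing one half. ROC points are emitted at every distinct score
#' threshold, so the trapezoidal area under the returned points equals the
#' rank-statistic AUC exactly.
#'
#' @param scores Numeric decision values, larger = more positive-class-like.
#' @param labels Class labels (two classes required).
#' @param positive Label of the positive class (default `"AD"`; for
#'   logical/0-1 labels, `TRUE`/`1` is positive).
#' @return An object of class `roc_curve`: list with `auc` and a data frame
#'   `points` of `(threshold, fpr, tpr)`.
#' @export
roc_auc <- function(scores, labels, positive = "AD") {
  stopifnot(length(scores) == length(labels))
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    pos <- labels == 1
  } else {
    labels <- as.character(labels)
    if (!positive %in% labels) stopf("positive label '%s' absent from labels", positive)
    pos <- labels == positive
  }
  if (!any(pos) || all(pos)) stopf("both classes must be present")
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(scores == t & pos), numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(scores == t & !pos), numeric(1)))
  points <- data.frame(threshold = c(Inf, thr),
                       fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  structure(list(auc = auc, points = points, n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d positive, %d negative, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points) - 1L))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
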