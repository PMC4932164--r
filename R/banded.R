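#' Fit a two-threshold "banded" interval classifier to a single marker
#'
#' Some disease markers show a banded distribution: healthy values occupy an
#' interval while disease values fall on both flanks, so the normal range
#' has both an upper and a lower limit. This fits the rule "value in
#' `(lower, upper]` is healthy, outside is disease" by exhaustive search
#' over all threshold pairs taken at midpoints of sorted distinct values
#' (plus infinite bounds), maximizing accuracy; ties prefer the widest
#' interval. The best single-threshold accuracy (either orientation) is the
#' restriction of the same family to one infinite bound, so
#' `interval_accuracy >= best_single_threshold_accuracy` always.
#'
#' @param values Numeric marker values (e.g. corrected log2 expression).
#' @param labels Class labels; `positive` marks the disease class.
#' @param positive Disease label (default `"AD"`).
#' @param margin `is_banded` is `TRUE` when the interval rule beats the best
#'   single threshold by more than this margin (default 0.05).
#' @return An object of class `banded_fit` with `lower`, `upper`,
#'   `interval_accuracy`, `best_single_threshold_accuracy`, `is_banded`.
#' @export
fit_banded <- function(values, labels, positive = "AD", margin = 0.05) {
  stopifnot(length(values) == length(labels))
  labels <- as.character(labels)
  dis <- labels == positive
  if (!any(dis) || all(dis)) stopf("both classes must be present")
  distinct <- sort(unique(values))
  if (length(distinct) < 2L) stopf("degenerate feature: constant values")
  if (length(distinct) < 4L) stopf("need at least 4 distinct values")

  cuts <- c(-Inf, (distinct[-1] + distinct[-length(distinct)]) / 2, Inf)
  k <- length(cuts)
  n <- length(values)
  # H(c) = healthy values <= c ; D(c) = disease values <= c
  hv <- sort(values[!dis]); dv <- sort(values[dis])
  H <- findInterval(cuts, hv); D <- findInterval(cuts, dv)
  nH <- length(hv); nD <- length(dv)
  # accuracy(lo, hi) for lo < hi: healthy inside + disease outside
  io <- which(outer(seq_len(k), seq_len(k), "<"), arr.ind = TRUE)
  lo <- io[, 1L]; hi <- io[, 2L]
  acc <- ((H[hi] - H[lo]) + (nD - (D[hi] - D[lo]))) / n
  width <- cuts[hi] - cuts[lo]
  best <- which(acc == max(acc))
  best <- best[order(-width[best], cuts[lo][best])][1L]

  single <- lo == 1L | hi == k
  best_single <- max(acc[single])

  interval_accuracy <- acc[best]
  structure(list(lower = cuts[lo[best]], upper = cuts[hi[best]],
                 interval_accuracy = interval_accuracy,
                 best_single_threshold_accuracy = best_single,
                 is_banded = interval_accuracy > best_single + margin,
                 margin = margin, n = n, positive = positive),
            class = "banded_fit")
}

#' @export
print.banded_fit <- function(x, ...) {
  cat(sprintf("<banded_fit> healthy range (%.4g, %.4g], accuracy %.3f (best single threshold %.3f)\n",
              x$lower, x$upper, x$interval_accuracy,
              x$best_single_threshold_accuracy))
  cat(sprintf("  banded pattern: %s (margin %g)\n", x$is_banded, x$margin))
  invisible(x)
}

#' @export
predict.banded_fit <- function(object, newdata, ...) {
  inside <- newdata > object$lower & newdata <= object$upper
  ifelse(inside, "HEALTHY", object$positive)
}
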