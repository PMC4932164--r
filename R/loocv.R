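#' Leave-one-out cross-validation accuracy of a panel SVM
#'
#' For each sample, the classifier is trained on the remaining `n - 1`
#' samples (re-resolving `gamma` and the standardization statistics on that
#' training fold only, so nothing leaks from the held-out sample) and the
#' held-out sample is predicted. The returned accuracy is the fraction of
#' correct predictions and is deterministic given the inputs and spec.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Two-class labels; each class needs at least two samples.
#' @param spec An [svm_spec()].
#' @return Accuracy as a fraction in `[0, 1]`.
#' @export
loocv_accuracy <- function(X, y, spec = svm_spec()) {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  if (n < 3L) stopf("LOOCV needs at least 3 samples, have %d", n)
  tab <- table(y)
  if (length(tab) != 2L) stopf("LOOCV needs exactly two classes, found %d", length(tab))
  if (any(tab < 2L))
    stopf("class '%s' has fewer than 2 samples", names(tab)[which.min(tab)])
  lev <- c(intersect(spec$positive, names(tab)), setdiff(names(tab), spec$positive))
  yf <- factor(y, levels = lev)
  gamma <- resolve_gamma(spec, ncol(X))

  yint <- as.integer(yf)
  correct <- 0L
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    if (spec$standardize) {
      st <- scale_stats(Xtr)
      Xtr <- apply_scale(Xtr, st)
      xi <- (X[i, ] - st$center) / st$scale
    } else xi <- X[i, ]
    fit <- svm_fit_fast(Xtr, yint[-i], gamma, spec$cost)
    pred_int <- if (svm_decide_fast(fit, xi) > 0) fit$labels[1L] else fit$labels[2L]
    if (pred_int == yint[i]) correct <- correct + 1L
  }
  correct / n
}

#' Rank features by single-feature LOOCV accuracy
#'
#' Every feature is scored by the LOOCV accuracy of an SVM trained on that
#' feature alone; the result is sorted in decreasing accuracy with ties kept
#' in original column order (stable sort). The top of this table is the
#' single-marker ranking reported for a discovery cohort.
#'
#' @param ds An [expr_dataset()] restricted to two diagnosis classes, or a
#'   numeric matrix (then `y` is required).
#' @param spec An [svm_spec()].
#' @param y Class labels when `ds` is a matrix.
#' @param top_k Optional: return only the first `top_k` rows.
#' @return Data frame with columns `rank`, `feature_id`, `gene_symbol`,
#'   `loocv_accuracy`.
#' @export
rank_single_features <- function(ds, spec = svm_spec(), y = NULL, top_k = NULL) {
  if (inherits(ds, "expr_dataset")) {
    X <- ds$values
    y <- ds$sample_meta$diagnosis
    sym <- ds$feature_meta$gene_symbol
  } else {
    X <- as.matrix(ds)
    if (is.null(y)) stopf("`y` is required when `ds` is a matrix")
    sym <- rep(NA_character_, ncol(X))
  }
  if (ncol(X) < 1L) stopf("dataset has no features")
  acc <- vapply(seq_len(ncol(X)), function(j)
    loocv_accuracy(X[, j, drop = FALSE], y, spec), numeric(1))
  ord <- order(-acc, seq_along(acc))
  out <- data.frame(rank = seq_along(ord),
                    feature_id = colnames(X)[ord],
                    gene_symbol = sym[ord],
                    loocv_accuracy = acc[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}
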