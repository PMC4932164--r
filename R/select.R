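#' SVM forward selection of a biomarker panel (SVMFS)
#'
#' Greedy forward search embedded in the fixed-configuration radial SVM: the
#' first panel member is the single feature with the highest LOOCV accuracy;
#' at each later round every remaining feature is evaluated as an addition
#' to the current panel and the best-scoring addition is included only if it
#' improves the LOOCV accuracy by strictly more than `threshold` (zero by
#' default, so a non-improving feature terminates the search). Ties are
#' broken towards the lowest original column index.
#'
#' @param ds An [expr_dataset()] restricted to exactly two diagnosis classes.
#' @param spec An [svm_spec()]; `gamma` is re-resolved for each candidate
#'   panel size.
#' @param threshold Minimum strict LOOCV-accuracy improvement required to
#'   continue (default 0).
#' @param max_size Optional cap on the panel size.
#' @return An object of class `selection_trace` with the ordered selected
#'   features, the LOOCV score after each inclusion, the termination reason
#'   and a final SVM trained on the whole cohort with the selected panel.
#'   Supports `print`, `summary`, `coef`, `plot`, `predict` and
#'   `as.data.frame`.
#' @seealso [svmtfs()] for the pre-ranked variant.
#' @export
svmfs <- function(ds, spec = svm_spec(), threshold = 0, max_size = Inf) {
  sel_env <- selection_setup(ds, spec)
  X <- sel_env$X; y <- sel_env$y
  p <- ncol(X)
  single <- vapply(seq_len(p), function(j)
    loocv_accuracy(X[, j, drop = FALSE], y, spec), numeric(1))
  best <- which.max(single)          # ties: lowest index
  selected <- best
  scores <- single[best]
  reason <- NULL
  repeat {
    remaining <- setdiff(seq_len(p), selected)
    if (!length(remaining)) { reason <- "pool_exhausted"; break }
    if (length(selected) >= max_size) { reason <- "max_size"; break }
    cand <- vapply(remaining, function(j)
      loocv_accuracy(X[, c(selected, j), drop = FALSE], y, spec), numeric(1))
    k <- which.max(cand)
    if (cand[k] - scores[length(scores)] > threshold) {
      selected <- c(selected, remaining[k])
      scores <- c(scores, cand[k])
    } else { reason <- "no_improvement"; break }
  }
  new_selection_trace(ds, spec, selected, scores, "SVMFS", threshold, reason)
}

#' SVM top-forward selection of a biomarker panel (SVMTFS)
#'
#' Variant of [svmfs()] that first ranks all features by single-feature
#' LOOCV accuracy and then considers candidates strictly in that order: the
#' candidate at round `k` is the `k`-th ranked feature regardless of the
#' current panel. The inclusion and termination rule is identical to SVMFS.
#'
#' @inheritParams svmfs
#' @param skip_nonimproving If `TRUE`, a non-improving ranked candidate is
#'   skipped and the next one tried instead of terminating the search
#'   (default `FALSE`: terminate).
#' @return A `selection_trace` (see [svmfs()]).
#' @export
svmtfs <- function(ds, spec = svm_spec(), threshold = 0, max_size = Inf,
                   skip_nonimproving = FALSE) {
  sel_env <- selection_setup(ds, spec)
  X <- sel_env$X; y <- sel_env$y
  p <- ncol(X)
  single <- vapply(seq_len(p), function(j)
    loocv_accuracy(X[, j, drop = FALSE], y, spec), numeric(1))
  ranking <- order(-single, seq_len(p))
  selected <- ranking[1L]
  scores <- single[ranking[1L]]
  reason <- NULL
  k <- 2L
  repeat {
    if (k > p) { reason <- "pool_exhausted"; break }
    if (length(selected) >= max_size) { reason <- "max_size"; break }
    cand <- ranking[k]
    acc <- loocv_accuracy(X[, c(selected, cand), drop = FALSE], y, spec)
    if (acc - scores[length(scores)] > threshold) {
      selected <- c(selected, cand)
      scores <- c(scores, acc)
      k <- k + 1L
    } else if (skip_nonimproving) {
      k <- k + 1L
    } else { reason <- "no_improvement"; break }
  }
  new_selection_trace(ds, spec, selected, scores, "SVMTFS", threshold, reason)
}

selection_setup <- function(ds, spec) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (ncol(ds$values) < 1L) stopf("dataset has no features")
  y <- as.character(ds$sample_meta$diagnosis)
  lev <- unique(y)
  if (length(lev) < 2L)
    stopf("selection needs two diagnosis classes, found only '%s'", lev[1])
  if (length(lev) > 2L)
    stopf("selection needs exactly two diagnosis classes; filter first (found %s)",
          paste(lev, collapse = ", "))
  list(X = ds$values, y = y)
}

new_selection_trace <- function(ds, spec, selected, scores, method,
                                threshold, reason) {
  ids <- ds$feature_meta$feature_id[selected]
  final <- train_svm(ds$values[, selected, drop = FALSE],
                     ds$sample_meta$diagnosis, spec)
  structure(list(selected = ids,
                 gene_symbol = ds$feature_meta$gene_symbol[selected],
                 scores = unname(scores),
                 method = method, threshold = threshold,
                 terminated_reason = reason,
                 spec = spec, n_samples = nrow(ds$values),
                 n_features_pool = ncol(ds$values),
                 final_model = final),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %s: %d-feature panel, final LOOCV accuracy %.3f\n",
              x$method, length(x$selected), x$scores[length(x$scores)]))
  print(as.data.frame(x), row.names = FALSE)
  cat(sprintf("terminated: %s (threshold %g, pool of %d features, n = %d)\n",
              x$terminated_reason, x$threshold, x$n_features_pool, x$n_samples))
  invisible(x)
}

#' @export
summary.selection_trace <- function(object, ...) {
  out <- as.data.frame(object)
  out$improvement <- c(NA, diff(object$scores))
  structure(list(table = out, method = object$method,
                 reason = object$terminated_reason,
                 final = object$scores[length(object$scores)]),
            class = "summary.selection_trace")
}

#' @export
print.summary.selection_trace <- function(x, ...) {
  cat(sprintf("%s selection, final LOOCV accuracy %.3f (%s)\n",
              x$method, x$final, x$reason))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.selection_trace <- function(x, ...) {
  data.frame(round = seq_along(x$selected), feature_id = x$selected,
             gene_symbol = x$gene_symbol, loocv_accuracy = x$scores,
             stringsAsFactors = FALSE)
}

#' @export
coef.selection_trace <- function(object, ...) {
  stats::setNames(object$scores, object$selected)
}

#' @export
plot.selection_trace <- function(x, ...) {
  graphics::plot(seq_along(x$scores), x$scores, type = "b", pch = 19,
                 xlab = "panel size", ylab = "LOOCV accuracy",
                 ylim = c(min(x$scores) - 0.02, 1),
                 main = sprintf("%s selection trace", x$method), ...)
  graphics::text(seq_along(x$scores), x$scores,
                 labels = ifelse(is.na(x$gene_symbol), x$selected, x$gene_symbol),
                 pos = 1, cex = 0.7)
  invisible(x)
}

#' @export
predict.selection_trace <- function(object, newdata, ...) {
  predict(object$final_model, newdata, ...)
}

#' Serialize a selection trace
#'
#' Writes the per-round table as TSV and a JSON sidecar with the method,
#' threshold, classifier configuration and termination reason.
#'
#' @param trace A `selection_trace`.
#' @param path_prefix Output path prefix; `<prefix>.tsv` and
#'   `<prefix>.json` are written.
#' @param seed Optional seed recorded in the sidecar.
#' @export
write_trace <- function(trace, path_prefix, seed = NULL) {
  write_tsv_full(as.data.frame(trace), paste0(path_prefix, ".tsv"))
  side <- list(method = trace$method, threshold = trace$threshold,
               terminated_reason = trace$terminated_reason,
               spec = unclass(trace$spec), n_samples = trace$n_samples,
               n_features_pool = trace$n_features_pool,
               final_loocv_accuracy = trace$scores[length(trace$scores)])
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path_prefix)
}
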