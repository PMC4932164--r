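#' Stratified random split scheme for repeated cross-validation
#'
#' The discovery evaluation draws a fixed number of training samples per
#' class uniformly without replacement, trains on the draw and tests on the
#' remainder, repeated many times (the study design: 30 AD + 30 healthy in
#' training, 5000 repeats; the validation-cohort design uses 20 + 20).
#'
#' @param n_train_pos,n_train_neg Per-class training counts.
#' @param n_repeats Number of random splits (default 5000).
#' @param seed Master seed; repeat `i` draws from substream `seed + i`, so
#'   enlarging `n_repeats` never reshuffles earlier repeats.
#' @return An object of class `split_scheme`.
#' @export
split_scheme <- function(n_train_pos = 30, n_train_neg = 30,
                         n_repeats = 5000, seed = 1) {
  stopifnot(is_count(n_train_pos), is_count(n_train_neg),
            is_count(n_repeats), is_count(seed, min = 0))
  structure(list(n_train_pos = as.integer(n_train_pos),
                 n_train_neg = as.integer(n_train_neg),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "split_scheme")
}

#' Repeated stratified-split evaluation of a fixed panel
#'
#' For each repeat, per-class training samples are drawn without
#' replacement, the panel SVM is trained on the draw and the held-out
#' remainder is predicted; the full metric panel (plus AUC from decision
#' scores) is computed per repeat. Metrics undefined in a repeat (zero
#' denominator) are excluded from that metric's average and counted.
#'
#' @param ds An [expr_dataset()] with two diagnosis classes.
#' @param panel Character vector of feature ids.
#' @param spec An [svm_spec()].
#' @param scheme A [split_scheme()].
#' @return An object of class `repeated_cv`: list with `summary` (per-metric
#'   means), `per_repeat` (one row per repeat with counts and metrics),
#'   `n_undefined` (per-metric exclusion counts), `scheme`, `panel`.
#' @export
repeated_split_cv <- function(ds, panel, spec = svm_spec(), scheme = split_scheme()) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(scheme, "split_scheme"))
  missing <- setdiff(panel, ds$feature_meta$feature_id)
  if (length(missing))
    stopf("panel features missing from dataset: %s", paste(missing, collapse = ", "))
  X <- ds$values[, match(panel, ds$feature_meta$feature_id), drop = FALSE]
  y <- as.character(ds$sample_meta$diagnosis)
  pos_idx <- which(y == spec$positive)
  neg_idx <- which(y != spec$positive)
  if (length(pos_idx) < scheme$n_train_pos + 1L)
    stopf("class '%s' has %d samples; need > %d", spec$positive,
          length(pos_idx), scheme$n_train_pos)
  if (length(neg_idx) < scheme$n_train_neg + 1L)
    stopf("negative class has %d samples; need > %d",
          length(neg_idx), scheme$n_train_neg)

  rows <- vector("list", scheme$n_repeats)
  for (i in seq_len(scheme$n_repeats)) {
    set.seed(derive_seed(scheme$seed, i))
    tr <- c(sample(pos_idx, scheme$n_train_pos),
            sample(neg_idx, scheme$n_train_neg))
    te <- setdiff(seq_along(y), tr)
    fit <- train_svm(X[tr, , drop = FALSE], y[tr], spec)
    pr <- predict(fit, X[te, , drop = FALSE])
    cc <- confusion_counts(y[te], pr$class, spec$positive)
    m <- metrics_from_counts(cc)
    if (length(unique(y[te])) == 2L)
      m["auc"] <- roc_auc(pr$score, y[te], spec$positive)$auc
    rows[[i]] <- c(repeat_ = i, tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
                   unclass(m))
  }
  per_repeat <- as.data.frame(do.call(rbind, rows))
  metric_cols <- c("sensitivity", "specificity", "ppv", "npv", "fdr",
                   "for_rate", "accuracy", "auc")
  means <- vapply(metric_cols, function(cn) mean(per_repeat[[cn]], na.rm = TRUE),
                  numeric(1))
  n_undef <- vapply(metric_cols, function(cn) sum(is.na(per_repeat[[cn]])),
                    integer(1))
  if (any(n_undef > 0))
    msgf("undefined metric values excluded from averages: %s",
         paste(sprintf("%s=%d", metric_cols[n_undef > 0], n_undef[n_undef > 0]),
               collapse = ", "))
  summary <- means
  class(summary) <- "metric_set"
  structure(list(summary = summary, per_repeat = per_repeat,
                 n_undefined = n_undef, scheme = scheme, panel = panel),
            class = "repeated_cv")
}

#' @export
print.repeated_cv <- function(x, ...) {
  cat(sprintf("<repeated_cv> panel {%s}, %d repeats of %d+%d training draws\n",
              paste(x$panel, collapse = ", "), x$scheme$n_repeats,
              x$scheme$n_train_pos, x$scheme$n_train_neg))
  print(x$summary)
  invisible(x)
}

#' Cross-cohort validation of a panel
#'
#' Trains once on all samples of the discovery cohort and predicts every
#' sample of an independent validation cohort, returning the metric panel
#' with AUC from the decision scores. Panel features are matched in the test
#' cohort by gene symbol first (so the validation cohort may be a different
#' platform) and by feature id second; a feature matching neither is an
#' error.
#'
#' @param train_ds,test_ds [expr_dataset()] cohorts with two diagnosis
#'   classes.
#' @param panel Character vector of feature ids in `train_ds`.
#' @param spec An [svm_spec()].
#' @return List with `metrics` (a `metric_set` including `auc`), `counts`,
#'   `roc`, `matched` (the feature correspondence used), and `scores`.
#' @export
cross_cohort_validate <- function(train_ds, test_ds, panel, spec = svm_spec()) {
  stopifnot(inherits(train_ds, "expr_dataset"), inherits(test_ds, "expr_dataset"))
  tr_idx <- match(panel, train_ds$feature_meta$feature_id)
  if (anyNA(tr_idx))
    stopf("panel features missing from training cohort: %s",
          paste(panel[is.na(tr_idx)], collapse = ", "))
  sym <- toupper(train_ds$feature_meta$gene_symbol[tr_idx])
  test_sym <- toupper(test_ds$feature_meta$gene_symbol)
  te_idx <- integer(length(panel))
  for (i in seq_along(panel)) {
    hit <- if (!is.na(sym[i])) which(test_sym == sym[i]) else integer(0)
    if (!length(hit)) hit <- which(test_ds$feature_meta$feature_id == panel[i])
    if (!length(hit)) { te_idx[i] <- NA_integer_ } else te_idx[i] <- hit[1L]
  }
  if (anyNA(te_idx))
    stopf("panel features missing from validation cohort: %s",
          paste(panel[is.na(te_idx)], collapse = ", "))
  Xtr <- train_ds$values[, tr_idx, drop = FALSE]
  Xte <- test_ds$values[, te_idx, drop = FALSE]
  colnames(Xte) <- colnames(Xtr)
  ytr <- as.character(train_ds$sample_meta$diagnosis)
  yte <- as.character(test_ds$sample_meta$diagnosis)
  fit <- train_svm(Xtr, ytr, spec)
  pr <- predict(fit, Xte)
  cc <- confusion_counts(yte, pr$class, spec$positive)
  m <- metrics_from_counts(cc)
  roc <- NULL
  if (length(unique(yte)) == 2L) {
    roc <- roc_auc(pr$score, yte, spec$positive)
    m["auc"] <- roc$auc
  }
  list(metrics = m, counts = cc, roc = roc,
       matched = data.frame(panel = panel,
                            test_feature = test_ds$feature_meta$feature_id[te_idx],
                            gene_symbol = sym, stringsAsFactors = FALSE),
       scores = pr)
}

#' Per-group LOOCV of a panel
#'
#' Runs [loocv_accuracy()] independently within each level of a grouping
#' field (e.g. brain region), producing one row per group. Groups with fewer
#' than two samples in either class are reported as skipped rather than
#' failing the whole table.
#'
#' @param ds An [expr_dataset()] whose sample metadata carries the group
#'   field.
#' @param panel Character vector of feature ids.
#' @param spec An [svm_spec()].
#' @param group_field Name of the sample-metadata column (default
#'   `"group"`).
#' @return Data frame with columns `group`, `n_pos`, `n_neg`, `accuracy`,
#'   `skipped`.
#' @export
grouped_loocv <- function(ds, panel, spec = svm_spec(), group_field = "group") {
  stopifnot(inherits(ds, "expr_dataset"))
  grp <- ds$sample_meta[[group_field]]
  if (is.null(grp)) stopf("sample metadata has no column '%s'", group_field)
  idx <- match(panel, ds$feature_meta$feature_id)
  if (anyNA(idx))
    stopf("panel features missing from dataset: %s",
          paste(panel[is.na(idx)], collapse = ", "))
  y <- as.character(ds$sample_meta$diagnosis)
  groups <- unique(grp[!is.na(grp)])
  rows <- lapply(groups, function(g) {
    s <- which(grp == g)
    npos <- sum(y[s] == spec$positive); nneg <- sum(y[s] != spec$positive)
    if (npos < 2L || nneg < 2L)
      return(data.frame(group = g, n_pos = npos, n_neg = nneg,
                        accuracy = NA_real_, skipped = TRUE))
    acc <- loocv_accuracy(ds$values[s, idx, drop = FALSE], y[s], spec)
    data.frame(group = g, n_pos = npos, n_neg = nneg,
               accuracy = acc, skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlations of panel markers
#'
#' Returns the correlation matrix of the given features over all samples and
#' within each diagnosis class with at least three samples. A zero-variance
#' feature within a stratum yields `NA` for its pairs. Strongly correlated
#' banded markers (|r| near 1 within the disease class) indicate that flank
#' membership co-occurs across markers.
#'
#' @param ds An [expr_dataset()].
#' @param features Character vector of feature ids.
#' @return Named list of correlation matrices: `overall` plus one per
#'   diagnosis class.
#' @export
panel_correlations <- function(ds, features) {
  stopifnot(inherits(ds, "expr_dataset"))
  idx <- match(features, ds$feature_meta$feature_id)
  if (anyNA(idx))
    stopf("features missing from dataset: %s",
          paste(features[is.na(idx)], collapse = ", "))
  X <- ds$values[, idx, drop = FALSE]
  cor_na <- function(M) {
    if (nrow(M) < 3L) return(NULL)
    sds <- apply(M, 2L, stats::sd)
    r <- suppressWarnings(stats::cor(M))
    r[sds == 0, ] <- NA_real_; r[, sds == 0] <- NA_real_
    diag(r) <- ifelse(sds == 0, NA_real_, 1)
    r
  }
  out <- list(overall = cor_na(X))
  for (d in unique(ds$sample_meta$diagnosis)) {
    r <- cor_na(X[ds$sample_meta$diagnosis == d, , drop = FALSE])
    if (!is.null(r)) out[[d]] <- r
  }
  out
}
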