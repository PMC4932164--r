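# Shared fixtures built in code.

# Tiny two-class dataset with well-separated clusters.
make_separable <- function(n_pos = 10, n_neg = 10, p = 2, gap = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_pos * p), n_pos, p) + gap,
             matrix(rnorm(n_neg * p), n_neg, p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(c("AD", "CONTROL"), c(n_pos, n_neg)))
}

# Minimal expr_dataset wrapper around a matrix.
make_dataset <- function(X, y, state = "LOG2", gene = colnames(X),
                         age = NULL, gender = NULL, group = NULL) {
  n <- nrow(X)
  rownames(X) <- sprintf("S%03d", seq_len(n))
  meta <- data.frame(sample_id = rownames(X), diagnosis = y,
                     age = age %||% NA_real_,
                     gender = gender %||% NA_character_,
                     cohort = "test",
                     group = group %||% NA_character_,
                     stringsAsFactors = FALSE)
  fmeta <- data.frame(feature_id = colnames(X), gene_symbol = gene,
                      stringsAsFactors = FALSE)
  expr_dataset(X, meta, fmeta, state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force LOOCV oracle through the public train_svm/predict interface.
loocv_oracle <- function(X, y, spec = svm_spec()) {
  n <- nrow(X)
  correct <- 0L
  for (i in seq_len(n)) {
    fit <- train_svm(X[-i, , drop = FALSE], y[-i], spec)
    pr <- predict(fit, X[i, , drop = FALSE])
    if (pr$class == y[i]) correct <- correct + 1L
  }
  correct / n
}

# Brute-force AUC oracle: pair counting with half credit for ties.
auc_oracle <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Small synthetic spec used where the full default cohort would be slow.
small_spec <- function(n_noise = 20, ...) {
  synthetic_spec(n_noise_features = n_noise, ...)
}

# Preprocess a generated cohort the way the discovery pipeline does.
prep_cohort <- function(ds, correct = TRUE) {
  lg <- floor_log_transform(filter_diagnoses(ds))
  if (!correct) return(lg)
  # rlm emits convergence warnings on floored background features; the
  # non-converged features pass through flagged, which is the contract
  suppressWarnings(suppressMessages(
    apply_correction(lg, fit_robust_correction(lg))))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
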