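#' Floor-at-one and log2 transform
#'
#' Expression values smaller than one are set to one and a base-2 logarithm
#' is applied, so all transformed values are non-negative. The transform is
#' monotone and, through the floor, maps the sub-unit tail of array
#' intensities to zero.
#'
#' @param ds An [expr_dataset()] with `transform_state = "RAW"`.
#' @return The dataset with log2 values and `transform_state = "LOG2"`.
#' @export
floor_log_transform <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (ds$transform_state != "RAW")
    stopf("floor_log_transform expects a RAW dataset, got %s", ds$transform_state)
  out <- ds
  out$values <- log2(pmax(ds$values, 1))
  out$transform_state <- "LOG2"
  out
}

#' Fit per-feature robust age/gender correction models
#'
#' For each feature, a Huber M-estimator linear regression (iteratively
#' reweighted least squares, tuning constant 1.345, MAD scale) of the log2
#' expression value on age (years, continuous) and gender (0/1 indicator,
#' reference level first alphabetically) is fitted over the samples with
#' complete covariates. Features whose fit fails or is degenerate are flagged
#' `converged = FALSE` with zero coefficients, so that applying the model
#' passes them through unchanged.
#'
#' @param ds An [expr_dataset()] with `transform_state = "LOG2"`.
#' @param maxit,acc IRLS iteration cap and convergence tolerance passed to
#'   the M-estimator.
#' @return An object of class `correction_model`: a data frame with columns
#'   `feature_id`, `intercept`, `age_coef`, `gender_coef`, `n_used`,
#'   `converged`, plus attributes recording the gender coding.
#' @export
fit_robust_correction <- function(ds, maxit = 50, acc = 1e-8) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (ds$transform_state != "LOG2")
    stopf("fit_robust_correction expects a LOG2 dataset, got %s", ds$transform_state)
  age <- as.numeric(ds$sample_meta$age)
  gender <- as.character(ds$sample_meta$gender)
  complete <- !is.na(age) & !is.na(gender) & nzchar(gender)
  n_used <- sum(complete)
  if (n_used == 0L) stopf("no sample has complete age and gender")
  if (n_used < 3L) stopf("need >= 3 samples with complete covariates, have %d", n_used)

  glev <- sort(unique(gender[complete]))
  gind <- as.numeric(gender == glev[length(glev)])   # 0 for reference level
  if (length(glev) > 2L)
    stopf("gender must have at most two levels, found: %s", paste(glev, collapse = ", "))
  X <- cbind(`(Intercept)` = 1, age = age, gender = gind)[complete, , drop = FALSE]
  age_ok <- stats::sd(X[, "age"]) > 0
  gen_ok <- stats::sd(X[, "gender"]) > 0
  use <- c(TRUE, age_ok, gen_ok)
  degenerate <- !age_ok && !gen_ok

  p <- ncol(ds$values)
  intercept <- age_coef <- gender_coef <- numeric(p)
  converged <- logical(p)
  for (j in seq_len(p)) {
    y <- ds$values[complete, j]
    if (degenerate || stats::sd(y) == 0) {
      # constant response or no usable covariate: identity pass-through
      intercept[j] <- mean(y); converged[j] <- !degenerate && stats::sd(y) == 0
      if (degenerate) converged[j] <- FALSE
      next
    }
    fit <- tryCatch(
      MASS::rlm(X[, use, drop = FALSE], y, psi = MASS::psi.huber,
                scale.est = "MAD", maxit = maxit, acc = acc),
      error = function(e) NULL)
    if (is.null(fit)) { intercept[j] <- mean(y); converged[j] <- FALSE; next }
    cf <- stats::setNames(numeric(3), c("(Intercept)", "age", "gender"))
    cf[colnames(X)[use]] <- stats::coef(fit)
    intercept[j] <- cf[["(Intercept)"]]
    age_coef[j] <- cf[["age"]]
    gender_coef[j] <- cf[["gender"]]
    converged[j] <- isTRUE(fit$converged)
    if (!converged[j]) { age_coef[j] <- 0; gender_coef[j] <- 0 }
  }
  n_fail <- sum(!converged)
  if (n_fail) msgf("%d feature(s) not corrected (IRLS not converged or degenerate design)", n_fail)
  structure(data.frame(feature_id = ds$feature_meta$feature_id,
                       intercept = intercept, age_coef = age_coef,
                       gender_coef = gender_coef, n_used = n_used,
                       converged = converged, stringsAsFactors = FALSE),
            gender_levels = glev, class = c("correction_model", "data.frame"))
}

#' Apply a fitted age/gender correction
#'
#' For every sample with complete covariates the corrected value is the
#' fitted intercept plus the residual, i.e. `observed - age_coef * age -
#' gender_coef * gender_indicator`. Samples with missing covariates keep
#' their observed values and are counted in a message. Features flagged
#' `converged = FALSE` pass through unchanged (their coefficients are zero).
#'
#' @param ds An [expr_dataset()] with `transform_state = "LOG2"`.
#' @param model A `correction_model` fitted on the same feature set.
#' @return The dataset with `transform_state = "CORRECTED"`.
#' @export
apply_correction <- function(ds, model) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(model, "correction_model"))
  if (ds$transform_state != "LOG2")
    stopf("apply_correction expects a LOG2 dataset, got %s", ds$transform_state)
  if (!identical(as.character(model$feature_id),
                 as.character(ds$feature_meta$feature_id)))
    stopf("feature set mismatch between dataset and correction model")
  age <- as.numeric(ds$sample_meta$age)
  gender <- as.character(ds$sample_meta$gender)
  glev <- attr(model, "gender_levels")
  gind <- as.numeric(gender == glev[length(glev)])
  complete <- !is.na(age) & !is.na(gender) & nzchar(gender)
  if (any(!complete))
    msgf("%d sample(s) with missing covariates kept uncorrected", sum(!complete))
  out <- ds
  adj <- outer(age, model$age_coef) + outer(gind, model$gender_coef)
  adj[!complete, ] <- 0
  out$values <- ds$values - adj
  out$transform_state <- "CORRECTED"
  out
}

#' Serialize a correction model for audit
#'
#' @param model A `correction_model`.
#' @param path Output TSV path.
#' @export
write_correction_model <- function(model, path) {
  write_tsv_full(as.data.frame(model), path)
  invisible(path)
}
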