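#' Fixed SVM classifier configuration
#'
#' The classifier configuration used throughout discovery and validation: a
#' C-classification support vector machine with radial-basis kernel
#' `K(u, v) = exp(-gamma * ||u - v||^2)`, cost 1 and `gamma` resolved as one
#' over the number of features of the panel being trained, mirroring the
#' defaults of the standard libsvm interface in R. Features are standardized
#' by training-set mean and standard deviation (a zero-variance feature gets
#' scale 1).
#'
#' @param cost Positive soft-margin cost, default 1.
#' @param gamma Either `"one_over_n_features"` (default) or a fixed positive
#'   number.
#' @param standardize Standardize features by training-set statistics
#'   (default `TRUE`).
#' @param positive Label of the positive (disease) class, default `"AD"`.
#' @return An object of class `svm_spec`.
#' @export
svm_spec <- function(cost = 1, gamma = "one_over_n_features",
                     standardize = TRUE, positive = "AD") {
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0)
    stopf("cost must be a positive number")
  if (is.character(gamma)) {
    if (!identical(gamma, "one_over_n_features"))
      stopf("gamma must be 'one_over_n_features' or a positive number")
  } else if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stopf("gamma must be 'one_over_n_features' or a positive number")
  structure(list(kernel = "radial", cost = cost, gamma = gamma,
                 standardize = isTRUE(standardize), positive = positive),
            class = "svm_spec")
}

resolve_gamma <- function(spec, n_features) {
  if (is.numeric(spec$gamma)) spec$gamma else 1 / n_features
}

#' @export
print.svm_spec <- function(x, ...) {
  g <- if (is.numeric(x$gamma)) format(x$gamma) else "1/n_features"
  cat(sprintf("<svm_spec> radial C-classification, cost=%g, gamma=%s, standardize=%s, positive=%s\n",
              x$cost, g, x$standardize, x$positive))
  invisible(x)
}

# Standardization statistics of a training matrix; zero-variance features
# get scale 1 so they pass through centred but undivided.
scale_stats <- function(X) {
  ctr <- colMeans(X)
  n <- nrow(X)
  sds <- sqrt(colSums((X - rep(ctr, each = n))^2) / (n - 1))
  zero <- !is.finite(sds) | sds == 0
  sds[zero] <- 1
  list(center = ctr, scale = sds, zero_variance = zero)
}

apply_scale <- function(X, st) {
  sweep(sweep(X, 2L, st$center, "-"), 2L, st$scale, "/")
}

# Lean shared call into the libsvm engine; X is already standardized.
svm_fit_raw <- function(Xs, y, gamma, cost) {
  e1071::svm(Xs, y, scale = FALSE, type = "C-classification",
             kernel = "radial", gamma = gamma, cost = cost, fitted = FALSE)
}

# Minimal-overhead radial C-SVC training through the libsvm engine,
# bypassing the interface layer; used in the LOOCV hot loop where the
# R-level wrapper's checks dominate run time. `y` is an integer vector of
# class codes (1, 2) in the factor's level order. Returns support vectors,
# dual coefficients, rho and the internal label order, enough to evaluate
# the decision function. Agreement with the standard interface is exact
# (same engine, same parameters) and is asserted in the test suite.
svm_engine <- local({
  sym <- NULL
  function() {
    if (is.null(sym)) {
      loadNamespace("e1071")
      sym <<- getNativeSymbolInfo("svmtrain", "e1071")
    }
    sym
  }
})

svm_fit_fast <- function(Xs, yint, gamma, cost) {
  n <- nrow(Xs); p <- ncol(Xs)
  err <- paste(rep(" ", 255), collapse = "")
  cret <- .C(svm_engine(), as.double(t(Xs)), as.integer(n), as.integer(p),
             as.double(yint), as.integer(0), as.integer(0),
             as.integer(0),         # type: C-classification
             as.integer(2),         # kernel: radial
             as.integer(3), as.double(gamma), as.double(0),
             as.double(cost), as.double(0.5), as.integer(0),
             as.double(0), as.integer(0),
             as.double(40),         # cache MB
             as.double(0.001),      # termination tolerance
             as.double(0.1), as.integer(1), as.integer(0),
             as.integer(FALSE), as.integer(FALSE),
             nclasses = integer(1), nr = integer(1), index = integer(n),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(n), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(0), ctotal1 = double(1),
             ctotal2 = double(1), error = err)
  if (!identical(cret$error, err)) stopf("svm training failed: %s", trimws(cret$error))
  nr <- cret$nr
  list(SV = Xs[cret$index[seq_len(nr)], , drop = FALSE],
       coefs = cret$coefs[seq_len(nr)], rho = cret$rho[1L],
       labels = cret$labels[1:2], gamma = gamma)
}

# Decision value of a fast fit for a single sample; positive values vote
# for the engine's first internal label (tie at zero goes to the second,
# matching the engine's own predictor).
svm_decide_fast <- function(fit, x) {
  d2 <- rowSums(sweep(fit$SV, 2L, x, "-")^2)
  sum(fit$coefs * exp(-fit$gamma * d2)) - fit$rho
}

#' Train the fixed-configuration SVM on a panel
#'
#' @param X Numeric matrix, samples x features (panel columns only).
#' @param y Class labels; must contain exactly two classes.
#' @param spec An [svm_spec()].
#' @return An object of class `panel_svm` exposing hard labels and
#'   real-valued decision scores via [predict.panel_svm()].
#' @export
train_svm <- function(X, y, spec = svm_spec()) {
  X <- as.matrix(X)
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) < 2L) stopf("training fold has one class: %s", lev[1])
  if (length(lev) > 2L) stopf("expected two classes, found %d", length(lev))
  if (nrow(X) != length(y)) stopf("X and y disagree on sample count")
  # positive level first so libsvm's decision values are oriented towards it
  lev <- c(intersect(spec$positive, lev), setdiff(lev, spec$positive))
  yf <- factor(y, levels = lev)
  st <- if (spec$standardize) scale_stats(X) else
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)),
         zero_variance = rep(FALSE, ncol(X)))
  if (any(st$zero_variance))
    msgf("%d zero-variance feature(s); scale set to 1", sum(st$zero_variance))
  Xs <- apply_scale(X, st)
  gamma <- resolve_gamma(spec, ncol(X))
  fit <- svm_fit_raw(Xs, yf, gamma, spec$cost)
  structure(list(fit = fit, spec = spec, stats = st, gamma = gamma,
                 features = colnames(X), levels = lev),
            class = "panel_svm")
}

#' Predict classes and decision scores from a trained panel SVM
#'
#' @param object A `panel_svm`.
#' @param newdata Matrix with the panel's feature columns (matched by name
#'   when named), or an [expr_dataset()].
#' @param ... Unused.
#' @return Data frame with columns `class` (predicted label) and `score`
#'   (decision value oriented so that larger means more positive-class-like).
#' @export
predict.panel_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "expr_dataset"))
    newdata <- newdata$values[, object$features, drop = FALSE]
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$features) &&
      all(object$features %in% colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  Xs <- apply_scale(newdata, object$stats)
  pr <- stats::predict(object$fit, Xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- dv[, 1L]
  # libsvm names the decision column "A/B" and scores towards A
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  if (!identical(first, object$spec$positive)) score <- -score
  data.frame(class = as.character(pr), score = unname(score),
             stringsAsFactors = FALSE)
}

#' @export
print.panel_svm <- function(x, ...) {
  cat(sprintf("<panel_svm> %d feature(s), gamma=%g, cost=%g, %d SV\n",
              length(x$features), x$gamma, x$spec$cost, x$fit$tot.nSV))
  invisible(x)
}
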