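make_eval_cohort <- function(seed = 51, n_noise = 10) {
  g <- generate_cohort(small_spec(n_noise), seed = seed)
  list(ds = prep_cohort(g$dataset, correct = FALSE), truth = g$truth)
}

test_that("a single repeat equals that split's metric panel and seeds reproduce", {
  fx <- make_eval_cohort()
  panel <- fx$truth$banded_feature_ids
  one <- repeated_split_cv(fx$ds, panel, scheme = split_scheme(30, 30, 1, 5))
  expect_equal(unname(one$summary[1:7]),
               unname(unlist(one$per_repeat[1, c("sensitivity", "specificity",
                                                 "ppv", "npv", "fdr", "for_rate",
                                                 "accuracy")])))
  again <- repeated_split_cv(fx$ds, panel, scheme = split_scheme(30, 30, 1, 5))
  expect_identical(one$per_repeat, again$per_repeat)
  # extending repeats preserves the earlier substreams
  ten <- repeated_split_cv(fx$ds, panel, scheme = split_scheme(30, 30, 10, 5))
  expect_identical(ten$per_repeat[1, ], one$per_repeat[1, ])
})

test_that("training-draw sizes and class-shortage errors are enforced", {
  fx <- make_eval_cohort()
  panel <- fx$truth$banded_feature_ids
  expect_error(repeated_split_cv(fx$ds, panel,
                                 scheme = split_scheme(50, 30, 1, 1)), "AD")
  expect_error(repeated_split_cv(fx$ds, c(panel, "absent_p9"),
                                 scheme = split_scheme(5, 5, 1, 1)), "absent_p9")
  cv <- repeated_split_cv(fx$ds, panel, scheme = split_scheme(20, 20, 3, 2))
  expect_equal(cv$per_repeat$tp + cv$per_repeat$fn, rep(30, 3))  # held-out AD
  expect_equal(cv$per_repeat$tn + cv$per_repeat$fp, rep(20, 3))
})

test_that("cross-cohort validation on the training cohort is resubstitution", {
  fx <- make_eval_cohort()
  panel <- fx$truth$banded_feature_ids
  cross <- cross_cohort_validate(fx$ds, fx$ds, panel)
  fit <- train_svm(fx$ds$values[, match(panel, fx$ds$feature_meta$feature_id)],
                   fx$ds$sample_meta$diagnosis)
  pr <- predict(fit, fx$ds)
  cc <- confusion_counts(fx$ds$sample_meta$diagnosis, pr$class)
  expect_equal(unname(cross$metrics["accuracy"]),
               (cc$tp + cc$tn) / nrow(fx$ds$values))
})

test_that("cross-cohort features match by gene symbol across platforms", {
  fx <- make_eval_cohort()
  panel <- fx$truth$banded_feature_ids
  other <- fx$ds
  # same genes under different probe ids, as on another platform
  other$feature_meta$feature_id <- paste0("alt_", other$feature_meta$feature_id)
  colnames(other$values) <- other$feature_meta$feature_id
  cross <- cross_cohort_validate(fx$ds, other, panel)
  expect_identical(cross$matched$test_feature, paste0("alt_", panel))
  # a panel feature absent everywhere errors with its name
  bad <- other
  bad$feature_meta$gene_symbol <- NA_character_
  expect_error(cross_cohort_validate(fx$ds, bad, panel), panel[1])
})

test_that("grouped LOOCV scores groups independently and skips small ones", {
  d <- make_separable(8, 8, gap = 6, seed = 61)
  X2 <- rbind(d$X, d$X)   # two identical groups
  ds <- make_dataset(X2, c(d$y, d$y),
                     group = rep(c("G1", "G2"), each = 16))
  tab <- grouped_loocv(ds, colnames(X2))
  expect_equal(tab$accuracy[1], tab$accuracy[2])
  expect_false(any(tab$skipped))
  # a group with one AD sample is skipped, not fatal
  ds2 <- make_dataset(rbind(d$X, d$X[c(1, 11, 12), ]),
                      c(d$y, d$y[c(1, 11, 12)]),
                      group = c(rep("G1", 16), rep("G2", 3)))
  tab2 <- grouped_loocv(ds2, colnames(d$X))
  expect_true(tab2$skipped[tab2$group == "G2"])
  expect_true(is.na(tab2$accuracy[tab2$group == "G2"]))
})

test_that("banded fit recovers a planted interval exactly", {
  set.seed(62)
  healthy <- runif(45, 2, 4)
  ad <- c(runif(22, 0, 1), runif(23, 5, 6))
  values <- c(ad, healthy)
  labels <- rep(c("AD", "CONTROL"), c(45, 45))
  bf <- fit_banded(values, labels)
  expect_equal(bf$interval_accuracy, 1)
  expect_true(bf$lower > 1 && bf$lower < 2)
  expect_true(bf$upper > 4 && bf$upper < 5)
  expect_true(bf$is_banded)
  expect_gte(bf$interval_accuracy, bf$best_single_threshold_accuracy)
  pred <- predict(bf, c(0.5, 3, 5.5))
  expect_identical(pred, c("AD", "HEALTHY", "AD"))
})

test_that("a one-sided marker is not banded and degenerate input errors", {
  set.seed(63)
  healthy <- rnorm(30, 0)
  ad <- rnorm(30, 4)
  bf <- fit_banded(c(ad, healthy), rep(c("AD", "CONTROL"), each = 30))
  expect_false(bf$is_banded)
  expect_equal(bf$interval_accuracy, bf$best_single_threshold_accuracy)
  expect_error(fit_banded(rep(1, 20), rep(c("AD", "CONTROL"), 10)),
               "degenerate")
  expect_error(fit_banded(rep(c(1, 2, 3), 7)[1:20],
                          rep(c("AD", "CONTROL"), 10)), "4 distinct")
})

test_that("banded accuracy on shuffled labels collapses to the majority rate", {
  set.seed(64)
  healthy <- runif(45, 2, 4)
  ad <- c(runif(22, 0, 1), runif(23, 5, 6))
  values <- c(ad, healthy)
  n <- length(values)
  maj <- 45 / n
  accs <- replicate(200, {
    fit_banded(values, sample(rep(c("AD", "CONTROL"), c(45, 45))))$interval_accuracy
  })
  # optimism above the majority rate stays within small-sample search noise
  expect_lt(mean(accs) - maj, 0.15)
  expect_gte(min(accs), maj - 1e-12)  # interval family contains "all healthy"
})

test_that("panel correlations recover exact algebraic cases", {
  set.seed(65)
  x <- rnorm(30)
  X <- cbind(a = x, b = x, c = -x, d = rnorm(30))
  ds <- make_dataset(X, rep(c("AD", "CONTROL"), each = 15))
  r <- panel_correlations(ds, c("a", "b", "c"))
  expect_equal(r$overall["a", "b"], 1)
  expect_equal(r$overall["a", "c"], -1)
  expect_named(r, c("overall", "AD", "CONTROL"))
  # zero-variance stratum gives NA pairs
  X2 <- cbind(a = x, flat = rep(1, 30))
  ds2 <- make_dataset(X2, rep(c("AD", "CONTROL"), each = 15))
  r2 <- quiet(panel_correlations(ds2, c("a", "flat")))
  expect_true(is.na(r2$overall["a", "flat"]))
})
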