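# A fixture where no single feature separates the classes but a planted
# pair does: each banded marker has noisy flanks, and the marker-specific
# noise puts different disease samples inside the normal band.
make_pair_cohort <- function(n_noise = 18, seed = 101) {
  spec <- synthetic_spec(n_pos = 25, n_neg = 20, n_noise_features = n_noise,
                         banded_markers = data.frame(
                           healthy_center = c(6, 7), healthy_halfwidth = c(1, 1),
                           flank_gap = c(0.5, 0.5), flank_fraction_low = c(0.5, 0.5),
                           within_class_sd = c(0.33, 0.33)),
                         target_correlations = 0.88,
                         one_sided_markers = data.frame(center = numeric(0),
                                                        effect_size = numeric(0),
                                                        sd = numeric(0)),
                         seed = seed)
  g <- generate_cohort(spec)
  list(ds = prep_cohort(g$dataset, correct = FALSE), truth = g$truth)
}

test_that("SVMFS recovers a planted pair, matching the exhaustive pair oracle", {
  fx <- make_pair_cohort()
  tr <- svmfs(fx$ds)
  planted <- fx$truth$banded_feature_ids
  expect_true(any(planted %in% tr$selected))
  expect_gte(length(tr$selected), 2)
  # final score strictly above every single-feature score
  singles <- vapply(seq_len(ncol(fx$ds$values)), function(j)
    loocv_accuracy(fx$ds$values[, j, drop = FALSE],
                   fx$ds$sample_meta$diagnosis), numeric(1))
  expect_gt(tr$scores[length(tr$scores)], max(singles))
  # the selected 2-feature prefix is the best pair containing the top single
  # feature (the greedy guarantee), verified against exhaustive search
  j1 <- match(tr$selected[1], fx$ds$feature_meta$feature_id)
  others <- setdiff(seq_len(ncol(fx$ds$values)), j1)
  pair_scores <- vapply(others, function(j)
    loocv_accuracy(fx$ds$values[, c(j1, j)], fx$ds$sample_meta$diagnosis),
    numeric(1))
  expect_equal(tr$scores[2], max(pair_scores))
  expect_identical(tr$selected[2],
                   fx$ds$feature_meta$feature_id[others[which.max(pair_scores)]])
})

test_that("selection traces always improve strictly beyond the threshold", {
  fx <- make_pair_cohort(n_noise = 10, seed = 202)
  for (tr in list(svmfs(fx$ds), svmtfs(fx$ds))) {
    expect_equal(length(tr$scores), length(tr$selected))
    if (length(tr$scores) > 1)
      expect_true(all(diff(tr$scores) > tr$threshold))
    expect_lte(length(tr$selected), ncol(fx$ds$values))
    expect_true(tr$terminated_reason %in%
                  c("no_improvement", "pool_exhausted", "max_size"))
  }
})

test_that("an unattainable threshold stops selection after one feature", {
  d <- make_separable(6, 6, p = 3)
  ds <- make_dataset(d$X, d$y)
  tr <- svmfs(ds, threshold = 1.1)
  expect_length(tr$selected, 1)
  expect_identical(tr$terminated_reason, "no_improvement")
})

test_that("a single-feature pool terminates by exhaustion", {
  d <- make_separable(6, 6, p = 1)
  ds <- make_dataset(d$X, d$y)
  tr <- svmfs(ds)
  expect_length(tr$selected, 1)
  expect_identical(tr$terminated_reason, "pool_exhausted")
})

test_that("a duplicated column is never added after its twin", {
  set.seed(31)
  x <- c(rnorm(10, 3), rnorm(10, 0))
  X <- cbind(a = x, b = x, c = rnorm(20))
  ds <- make_dataset(X, rep(c("AD", "CONTROL"), each = 10))
  tr <- svmfs(ds)
  expect_false(all(c("a", "b") %in% tr$selected))
  tr2 <- svmtfs(ds)
  expect_false(all(c("a", "b") %in% tr2$selected))
  # the duplicate ranks immediately after its twin yet adds no improvement
  expect_length(tr2$selected, 1)
})

test_that("SVMTFS considers candidates strictly in ranking order", {
  fx <- make_pair_cohort(n_noise = 10, seed = 303)
  rk <- rank_single_features(fx$ds)
  tr <- svmtfs(fx$ds)
  expect_identical(tr$selected[1], rk$feature_id[1])
  # every selected feature appears in ranking order
  pos <- match(tr$selected, rk$feature_id)
  expect_true(all(diff(pos) > 0))
  # when the two planted markers rank 1-2 and both improve, SVMFS and
  # SVMTFS agree on the first two picks
  tf <- svmfs(fx$ds)
  if (identical(sort(rk$feature_id[1:2]), sort(fx$truth$banded_feature_ids)) &&
      length(tr$selected) >= 2 && length(tf$selected) >= 2)
    expect_identical(tr$selected[1:2], tf$selected[1:2])
})

test_that("skip mode passes over non-improving ranked candidates", {
  set.seed(32)
  x <- c(rnorm(10, 3), rnorm(10, 0))
  X <- cbind(a = x, b = x, c = x + rnorm(20, 0, 2))
  ds <- make_dataset(X, rep(c("AD", "CONTROL"), each = 10))
  tr <- svmtfs(ds, skip_nonimproving = TRUE)
  expect_identical(tr$terminated_reason, "pool_exhausted")
})

test_that("selection requires a valid two-class dataset", {
  d <- make_separable(6, 6)
  ds1 <- make_dataset(d$X, rep("AD", 12))
  expect_error(svmfs(ds1), "two diagnosis classes")
  ds3 <- make_dataset(d$X, rep(c("AD", "CONTROL", "OTHER"), each = 4))
  expect_error(svmfs(ds3), "filter")
})

test_that("trace methods expose the fitted panel consistently", {
  fx <- make_pair_cohort(n_noise = 6, seed = 404)
  tr <- svmfs(fx$ds)
  df <- as.data.frame(tr)
  expect_named(df, c("round", "feature_id", "gene_symbol", "loocv_accuracy"))
  expect_equal(unname(coef(tr)), tr$scores)
  s <- summary(tr)
  expect_s3_class(s, "summary.selection_trace")
  pr <- predict(tr, fx$ds)
  expect_equal(nrow(pr), nrow(fx$ds$values))
  # serialization writes TSV + JSON sidecar
  pref <- tempfile()
  write_trace(tr, pref, seed = 1)
  expect_true(file.exists(paste0(pref, ".tsv")))
  side <- jsonlite::read_json(paste0(pref, ".json"))
  expect_identical(side$method, "SVMFS")
  expect_identical(side$terminated_reason, tr$terminated_reason)
})
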