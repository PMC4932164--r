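test_that("default cohort has the study's class sizes and is seed-stable", {
  g <- generate_cohort(synthetic_spec(n_noise_features = 15))
  expect_equal(nrow(g$dataset$values), 90)
  expect_equal(sum(g$dataset$sample_meta$diagnosis == "AD"), 50)
  expect_equal(sum(g$dataset$sample_meta$diagnosis == "CONTROL"), 40)
  expect_identical(g$dataset$transform_state, "RAW")
  expect_true(all(g$dataset$values > 0))
  g2 <- generate_cohort(synthetic_spec(n_noise_features = 15))
  expect_identical(g$dataset$values, g2$dataset$values)
  expect_identical(g$dataset$sample_meta, g2$dataset$sample_meta)
  # a different seed changes the draw
  g3 <- generate_cohort(synthetic_spec(n_noise_features = 15), seed = 99)
  expect_false(identical(g$dataset$values, g3$dataset$values))
})

test_that("cohort pair has the validation sizes and shared planted genes", {
  pair <- generate_cohort_pair(small_spec(10))
  expect_equal(sum(pair$validation$sample_meta$diagnosis == "AD"), 36)
  expect_equal(sum(pair$validation$sample_meta$diagnosis == "CONTROL"), 57)
  expect_identical(pair$discovery$feature_meta$gene_symbol,
                   pair$validation$feature_meta$gene_symbol)
})

test_that("infeasible or inconsistent specs fail before sampling", {
  expect_error(synthetic_spec(banded_markers = data.frame(
    healthy_center = c(6, 7, 8), healthy_halfwidth = 1, flank_gap = 0.3,
    flank_fraction_low = 0.5, within_class_sd = 0.33),
    target_correlations = 0.9), "3 pairwise")
  expect_error(synthetic_spec(target_correlations = 1.4), "not TRUE")
  expect_error(synthetic_spec(n_pos = 1), "not TRUE")
})

test_that("planted bands hold: healthy inside, disease outside", {
  inside_h <- outside_a <- numeric(0)
  spec <- synthetic_spec(n_noise_features = 5)
  for (seed in 1:10) {
    g <- generate_cohort(spec, seed = seed)
    lg <- floor_log_transform(g$dataset)
    ad <- lg$sample_meta$diagnosis == "AD"
    for (m in seq_len(nrow(spec$banded_markers))) {
      bm <- spec$banded_markers[m, ]
      v <- lg$values[, g$truth$banded_feature_ids[m]]
      band <- abs(v - bm$healthy_center) <= bm$healthy_halfwidth
      inside_h <- c(inside_h, mean(band[!ad]))
      outside_a <- c(outside_a, mean(!band[ad]))
    }
  }
  expect_gte(mean(inside_h), 0.95)
  expect_gte(mean(outside_a), 0.95)
})

test_that("noise features carry no class signal beyond the nominal rate", {
  g <- generate_cohort(synthetic_spec(), seed = 77)
  lg <- floor_log_transform(g$dataset)
  ad <- lg$sample_meta$diagnosis == "AD"
  noise_ids <- setdiff(lg$feature_meta$feature_id, g$truth$planted_feature_ids)
  p <- vapply(noise_ids, function(f)
    t.test(lg$values[ad, f], lg$values[!ad, f])$p.value, numeric(1))
  expect_lt(mean(p < 0.01), 0.05)   # ~1% expected, allow binomial slack
})

test_that("planted pair correlation matches the latent-factor closed form", {
  spec <- synthetic_spec(n_noise_features = 5)
  # correlations are read off age/gender-corrected values, as in the
  # analysis itself; the raw values carry confounder dilution
  rs <- vapply(1:20, function(seed) {
    g <- generate_cohort(spec, seed = seed)
    cds <- prep_cohort(g$dataset)
    ad <- cds$sample_meta$diagnosis == "AD"
    cor(cds$values[ad, g$truth$banded_feature_ids[1]],
        cds$values[ad, g$truth$banded_feature_ids[2]])
  }, numeric(1))
  pop <- generate_cohort(spec)$truth$population_correlations[1, 2]
  expect_equal(pop, 0.99, tolerance = 1e-12)
  expect_lt(max(abs(rs - 0.99)), 0.02)
})

test_that("three markers with the signed correlation pattern are feasible", {
  spec <- synthetic_spec(
    banded_markers = data.frame(healthy_center = c(6, 7, 6.5),
                                healthy_halfwidth = 1, flank_gap = 0.3,
                                flank_fraction_low = 0.5, within_class_sd = 0.33),
    target_correlations = c(0.99, -0.95, -0.94),
    n_noise_features = 5)
  g <- generate_cohort(spec, seed = 13)
  pop <- g$truth$population_correlations
  expect_equal(pop[1, 2], 0.99, tolerance = 0.005)
  expect_equal(pop[1, 3], -0.95, tolerance = 0.005)
  expect_equal(pop[2, 3], -0.94, tolerance = 0.005)
  lg <- floor_log_transform(g$dataset)
  ad <- lg$sample_meta$diagnosis == "AD"
  M <- lg$values[ad, g$truth$banded_feature_ids]
  r <- cor(M)
  expect_equal(r[1, 2], pop[1, 2], tolerance = 0.03)
  expect_equal(r[1, 3], pop[1, 3], tolerance = 0.03)
  expect_equal(r[2, 3], pop[2, 3], tolerance = 0.03)
})

test_that("age confounding closes the loop with the correction stage", {
  spec <- synthetic_spec(n_noise_features = 10, age_effect_sd = 0.03)
  g <- generate_cohort(spec, seed = 21)
  lg <- floor_log_transform(g$dataset)
  cds <- quiet(apply_correction(lg, fit_robust_correction(lg)))
  # the most strongly confounded noise features end up age-decorrelated;
  # features low enough to hit the floor are excluded (the floor is a
  # nonlinearity no linear correction can undo)
  beta <- g$truth$beta_age
  unfloored <- names(g$truth$feature_centers)[g$truth$feature_centers > 3]
  beta <- beta[intersect(names(beta), unfloored)]
  worst <- names(sort(abs(beta), decreasing = TRUE))[1:5]
  for (f in worst) {
    r_after <- cor(cds$values[, f], cds$sample_meta$age)
    expect_lt(abs(r_after), 0.05)
  }
})

test_that("zero shift makes the cohorts exchangeable draws", {
  spec <- small_spec(20)
  n_reject <- 0; n_tests <- 0
  for (seed in 1:40) {
    pair <- generate_cohort_pair(spec, seed = seed,
                                 shift = list(location = 0, scale = 1))
    da <- floor_log_transform(pair$discovery)
    va <- floor_log_transform(pair$validation)
    noise <- setdiff(da$feature_meta$feature_id, pair$truth$planted_feature_ids)
    # pool centred noise values so feature means cancel
    pool_d <- as.vector(scale(da$values[, noise], scale = FALSE))
    pool_v <- as.vector(scale(va$values[, noise], scale = FALSE))
    p <- suppressWarnings(ks.test(pool_d, pool_v)$p.value)
    n_tests <- n_tests + 1
    if (p < 0.01) n_reject <- n_reject + 1
  }
  expect_gte(1 - n_reject / n_tests, 0.95)
})

test_that("grouped cohorts confine the planted signal to signal groups", {
  spec <- small_spec(10)
  g <- generate_grouped_cohort(spec, n_groups = 4, signal_groups = c(1, 2),
                               seed = 31)
  ds <- prep_cohort(g$dataset, correct = FALSE)
  expect_equal(length(unique(ds$sample_meta$group)), 4)
  ad <- ds$sample_meta$diagnosis == "AD"
  f <- g$truth$banded_feature_ids[1]
  ctr <- spec$banded_markers$healthy_center[1]
  # banded flanks are symmetric, so signal shows as spread around the centre
  band_dev <- function(grp) mean(abs(ds$values[ds$sample_meta$group == grp & ad, f] - ctr))
  expect_gt(band_dev("G1"), 1)
  expect_gt(band_dev("G2"), 1)
  expect_lt(band_dev("G3"), 1)
  expect_lt(band_dev("G4"), 1)
  expect_error(generate_grouped_cohort(spec, n_groups = 1), "2 groups")
  expect_error(generate_grouped_cohort(spec, n_groups = 3, n_pos_group = 1),
               "2 samples")
})
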