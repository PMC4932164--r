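#' Parameterization of the synthetic protein-array cohorts
#'
#' Defines the generative model used to exercise every pipeline stage
#' without real cohort downloads. The defaults emulate the discovery-cohort
#' shape of the study design: 50 disease (AD) and 40 healthy serum samples,
#' a large background of uninformative features, two planted "banded"
#' markers whose healthy values occupy an interval while disease values
#' fall beyond a gap on either flank (flank membership shared across
#' markers through a latent variable, inducing the strong inter-marker
#' correlations seen in such data), one classic one-sided marker, and
#' linear age and gender confounding.
#'
#' @param n_pos,n_neg Discovery-class sizes (default 50 AD, 40 healthy).
#' @param n_pos_val,n_neg_val Validation-cohort class sizes (default 36,
#'   57).
#' @param n_noise_features Number of uninformative background features
#'   (default 200).
#' @param banded_markers Data frame, one row per banded marker, columns
#'   `healthy_center`, `healthy_halfwidth`, `flank_gap`,
#'   `flank_fraction_low`, `within_class_sd` (all in log2 units except the
#'   fraction).
#' @param target_correlations Pairwise Pearson targets among the planted
#'   banded markers, in the pair order (1,2), (1,3), (2,3), ... A single
#'   number suffices for two markers. Targets are induced through a shared
#'   single latent factor; magnitudes implying a loading above 1 are
#'   clamped at 0.9999.
#' @param one_sided_markers Data frame, one row per one-sided marker,
#'   columns `center`, `effect_size`, `sd` (log2 units; disease mean is
#'   shifted by `effect_size`).
#' @param age_range Sampling range of ages in years (default 60--90).
#' @param age_effect_sd,gender_effect_sd Standard deviations of the
#'   per-feature confounder coefficients (log2 units per year; log2 units).
#' @param noise_center_range,noise_sd Background feature log2 means are
#'   uniform in this range with this within-feature sd; the low end of the
#'   range puts roughly 5% of raw noise values below one so the floor rule
#'   is exercised.
#' @param cohort_shift List with `location` (log2 offset added to all
#'   features of the second cohort) and `scale` (spread multiplier around
#'   each feature's generating center), emulating a between-cohort
#'   normalization shift.
#' @param seed Integer master seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 50, n_neg = 40,
                           n_pos_val = 36, n_neg_val = 57,
                           n_noise_features = 200,
                           banded_markers = data.frame(
                             healthy_center = c(6, 7),
                             healthy_halfwidth = c(1, 1),
                             flank_gap = c(0.3, 0.3),
                             flank_fraction_low = c(0.5, 0.5),
                             within_class_sd = c(0.33, 0.33)),
                           target_correlations = 0.99,
                           one_sided_markers = data.frame(
                             center = 5, effect_size = 1.5, sd = 0.5),
                           age_range = c(60, 90),
                           age_effect_sd = 0.01,
                           gender_effect_sd = 0.1,
                           noise_center_range = c(0, 8),
                           noise_sd = 1,
                           cohort_shift = list(location = 1, scale = 1),
                           seed = 20160529) {
  stopifnot(n_pos >= 2, n_neg >= 2, n_pos_val >= 2, n_neg_val >= 2,
            n_noise_features >= 0)
  nb <- nrow(banded_markers)
  stopifnot(all(banded_markers$healthy_halfwidth > 0),
            all(banded_markers$flank_gap > 0),
            all(banded_markers$flank_fraction_low >= 0 &
                  banded_markers$flank_fraction_low <= 1),
            all(abs(target_correlations) <= 1))
  if (nb >= 2) {
    need <- nb * (nb - 1) / 2
    if (length(target_correlations) != need)
      stopf("need %d pairwise correlation targets for %d banded markers", need, nb)
  }
  structure(list(n_pos = n_pos, n_neg = n_neg, n_pos_val = n_pos_val,
                 n_neg_val = n_neg_val, n_noise_features = n_noise_features,
                 banded_markers = banded_markers,
                 target_correlations = target_correlations,
                 one_sided_markers = one_sided_markers,
                 age_range = age_range, age_effect_sd = age_effect_sd,
                 gender_effect_sd = gender_effect_sd,
                 noise_center_range = noise_center_range, noise_sd = noise_sd,
                 cohort_shift = cohort_shift, seed = seed),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d AD + %d healthy; %d banded + %d one-sided markers, %d noise features\n",
              x$n_pos, x$n_neg, nrow(x$banded_markers),
              nrow(x$one_sided_markers), x$n_noise_features))
  invisible(x)
}

# Single-factor loadings reproducing the pairwise correlation targets.
# For >= 3 markers the first loading is sqrt(r12*r13/r23) (signs handled
# separately); magnitudes are clamped to 0.9999 when the targets are not
# jointly attainable by one factor.
factor_loadings <- function(targets, nb) {
  if (nb == 1L) return(1)
  if (nb == 2L) {
    lam <- sqrt(abs(targets[1]))
    return(c(lam, sign(targets[1]) * lam))
  }
  R <- diag(nb)
  k <- 1L
  for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
    R[i, j] <- R[j, i] <- targets[k]; k <- k + 1L
  }
  lam <- numeric(nb)
  lam[1] <- sqrt(min(abs(R[1, 2] * R[1, 3] / R[2, 3]), 0.9999^2))
  for (m in 2:nb) lam[m] <- R[1, m] / lam[1]
  lam <- sign(lam) * pmin(abs(lam), 0.9999)
  lam
}

# Draw the log2-scale matrix of one cohort. Returns values plus generation
# records used for ground truth.
draw_log2_cohort <- function(spec, n_pos, n_neg) {
  n <- n_pos + n_neg
  diagnosis <- c(rep("AD", n_pos), rep("CONTROL", n_neg))
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  gender <- sample(rep(c("F", "M"), length.out = n))

  nb <- nrow(spec$banded_markers)
  ns <- nrow(spec$one_sided_markers)
  nn <- spec$n_noise_features
  p <- nb + ns + nn
  vals <- matrix(NA_real_, n, p)

  lam <- factor_loadings(spec$target_correlations, nb)
  pop_r <- outer(lam, lam); diag(pop_r) <- 1

  # shared latent flank variable of the disease class
  pl <- spec$banded_markers$flank_fraction_low[1]
  flank <- ifelse(stats::runif(n_pos) < pl, -1, 1)
  varF <- 4 * pl * (1 - pl)
  if (varF == 0) varF <- 1    # degenerate one-flank design: no shared spread

  centers <- numeric(p)
  for (m in seq_len(nb)) {
    bm <- spec$banded_markers[m, ]
    offset <- bm$healthy_halfwidth + bm$flank_gap
    rho <- abs(lam[m])
    sd_ad <- if (nb >= 2 && rho < 1) offset * sqrt(varF) * sqrt(1 / rho^2 - 1)
             else bm$within_class_sd
    healthy <- stats::rnorm(n_neg, bm$healthy_center, bm$within_class_sd)
    ad <- bm$healthy_center + sign(lam[m]) * flank * offset +
      stats::rnorm(n_pos, 0, sd_ad)
    vals[, m] <- c(ad, healthy)
    centers[m] <- bm$healthy_center
  }
  for (m in seq_len(ns)) {
    om <- spec$one_sided_markers[m, ]
    vals[, nb + m] <- c(stats::rnorm(n_pos, om$center + om$effect_size, om$sd),
                        stats::rnorm(n_neg, om$center, om$sd))
    centers[nb + m] <- om$center
  }
  if (nn > 0) {
    mu <- stats::runif(nn, spec$noise_center_range[1], spec$noise_center_range[2])
    vals[, nb + ns + seq_len(nn)] <-
      matrix(stats::rnorm(n * nn, mean = rep(mu, each = n), sd = spec$noise_sd), n, nn)
    centers[nb + ns + seq_len(nn)] <- mu
  }

  beta_age <- stats::rnorm(p, 0, spec$age_effect_sd)
  beta_gen <- stats::rnorm(p, 0, spec$gender_effect_sd)
  conf <- outer(age - mean(spec$age_range), beta_age) +
    outer(as.numeric(gender == "M"), beta_gen)
  vals <- vals + conf

  list(log2 = vals, diagnosis = diagnosis, age = age, gender = gender,
       centers = centers, flank = flank, loadings = lam, pop_r = pop_r,
       beta_age = beta_age, beta_gen = beta_gen)
}

synthetic_feature_meta <- function(spec) {
  nb <- nrow(spec$banded_markers)
  ns <- nrow(spec$one_sided_markers)
  nn <- spec$n_noise_features
  gene <- c(sprintf("BMK%d", seq_len(nb)),
            sprintf("OSM%d", seq_len(ns)),
            sprintf("NSE%04d", seq_len(nn)))
  data.frame(feature_id = paste0(gene, "_p1"), gene_symbol = gene,
             stringsAsFactors = FALSE)
}

assemble_cohort <- function(spec, draw, cohort_label, sample_prefix) {
  fmeta <- synthetic_feature_meta(spec)
  n <- length(draw$diagnosis)
  smeta <- data.frame(sample_id = sprintf("%s%03d", sample_prefix, seq_len(n)),
                      diagnosis = draw$diagnosis, age = draw$age,
                      gender = draw$gender, cohort = cohort_label,
                      group = NA_character_, stringsAsFactors = FALSE)
  raw <- 2^draw$log2
  dimnames(raw) <- list(smeta$sample_id, fmeta$feature_id)
  expr_dataset(raw, smeta, fmeta, "RAW")
}

ground_truth <- function(spec, draw) {
  fmeta <- synthetic_feature_meta(spec)
  nb <- nrow(spec$banded_markers)
  ns <- nrow(spec$one_sided_markers)
  list(planted_feature_ids = fmeta$feature_id[seq_len(nb + ns)],
       banded_feature_ids = fmeta$feature_id[seq_len(nb)],
       one_sided_feature_ids = fmeta$feature_id[nb + seq_len(ns)],
       banded_markers = spec$banded_markers,
       one_sided_markers = spec$one_sided_markers,
       loadings = draw$loadings,
       population_correlations = draw$pop_r,
       flank = draw$flank,
       feature_centers = stats::setNames(draw$centers, fmeta$feature_id),
       beta_age = stats::setNames(draw$beta_age, fmeta$feature_id),
       beta_gender = stats::setNames(draw$beta_gen, fmeta$feature_id))
}

#' Generate a synthetic discovery cohort
#'
#' Draws one cohort from the generative model of a [synthetic_spec()]:
#' raw-scale positive intensities whose log2 values carry the planted
#' banded markers (healthy inside an interval, disease beyond a gap on a
#' flank shared across markers), one-sided markers, an uninformative
#' background and linear age/gender confounding. Identical seeds give
#' bit-identical cohorts.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed override (defaults to `spec$seed`).
#' @param cohort Cohort label written into the sample metadata.
#' @return List with `dataset` (a raw-scale [expr_dataset()]) and `truth`
#'   (planted feature ids, generating parameters, latent flank assignment,
#'   population correlations).
#' @export
generate_cohort <- function(spec = synthetic_spec(), seed = spec$seed,
                            cohort = "discovery") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(seed, 0))
  draw <- draw_log2_cohort(spec, spec$n_pos, spec$n_neg)
  list(dataset = assemble_cohort(spec, draw, cohort, "S"),
       truth = ground_truth(spec, draw))
}

#' Generate a discovery/validation cohort pair
#'
#' The validation cohort is drawn from the same generative process with its
#' own class sizes (defaults 36 disease / 57 healthy) and a distributional
#' shift applied to all features in log2 space: values move by
#' `cohort_shift$location` and spread by `cohort_shift$scale` around each
#' feature's generating center, emulating cohorts normalized by different
#' procedures. Planted markers keep their gene symbols, so cross-cohort
#' matching works by symbol.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed override (defaults to `spec$seed`).
#' @param shift Optional override of `spec$cohort_shift`.
#' @return List with `discovery`, `validation` (both [expr_dataset()]) and
#'   `truth` (of the discovery draw; planted ids are shared).
#' @export
generate_cohort_pair <- function(spec = synthetic_spec(), seed = spec$seed,
                                 shift = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  shift <- shift %||% spec$cohort_shift
  disc <- generate_cohort(spec, seed = seed, cohort = "discovery")
  set.seed(derive_seed(seed, 104729))
  draw <- draw_log2_cohort(spec, spec$n_pos_val, spec$n_neg_val)
  ctr <- matrix(draw$centers, nrow = nrow(draw$log2), ncol = length(draw$centers),
                byrow = TRUE)
  draw$log2 <- ctr + shift$scale * (draw$log2 - ctr) + shift$location
  val <- assemble_cohort(spec, draw, "validation", "V")
  list(discovery = disc$dataset, validation = val, truth = disc$truth)
}

#' Generate a grouped cohort with group-restricted signal
#'
#' Emulates a multi-region validation design: samples come in `n_groups`
#' blocks and the planted-marker effects are present only in
#' `signal_groups`; in the remaining groups disease samples are drawn from
#' the healthy marker distributions, while the noise structure is shared.
#'
#' @param spec A [synthetic_spec()].
#' @param n_groups Number of groups (at least 2).
#' @param signal_groups Integer indices of groups carrying the planted
#'   signal.
#' @param n_pos_group,n_neg_group Per-group class sizes (default 15/12,
#'   approximating 87/74 split across six regions).
#' @param seed Seed override.
#' @return List with `dataset` (group field populated) and `truth`.
#' @export
generate_grouped_cohort <- function(spec = synthetic_spec(), n_groups = 6,
                                    signal_groups = c(1, 2),
                                    n_pos_group = 15, n_neg_group = 12,
                                    seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_groups < 2L) stopf("need at least 2 groups")
  if (!length(signal_groups)) stopf("signal_groups must be non-empty")
  if (n_pos_group < 2L || n_neg_group < 2L)
    stopf("need at least 2 samples per class per group")
  set.seed(derive_seed(seed, 7919))
  nb <- nrow(spec$banded_markers)
  ns <- nrow(spec$one_sided_markers)
  parts <- vector("list", n_groups)
  truth <- NULL
  for (g in seq_len(n_groups)) {
    draw <- draw_log2_cohort(spec, n_pos_group, n_neg_group)
    if (!(g %in% signal_groups)) {
      # overwrite disease rows of planted markers with healthy draws
      for (m in seq_len(nb)) {
        bm <- spec$banded_markers[m, ]
        draw$log2[seq_len(n_pos_group), m] <-
          stats::rnorm(n_pos_group, bm$healthy_center, bm$within_class_sd)
      }
      for (m in seq_len(ns)) {
        om <- spec$one_sided_markers[m, ]
        draw$log2[seq_len(n_pos_group), nb + m] <-
          stats::rnorm(n_pos_group, om$center, om$sd)
      }
    }
    if (is.null(truth)) truth <- ground_truth(spec, draw)
    ds <- assemble_cohort(spec, draw, "grouped", sprintf("G%d_", g))
    ds$sample_meta$group <- sprintf("G%d", g)
    parts[[g]] <- ds
  }
  values <- do.call(rbind, lapply(parts, function(d) d$values))
  smeta <- do.call(rbind, lapply(parts, function(d) d$sample_meta))
  truth$signal_groups <- sprintf("G%d", signal_groups)
  list(dataset = expr_dataset(values, smeta, parts[[1]]$feature_meta, "RAW"),
       truth = truth)
}
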