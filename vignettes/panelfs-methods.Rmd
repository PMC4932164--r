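---
title: "Discovering blood biomarker panels with SVM-embedded forward selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering blood biomarker panels with SVM-embedded forward selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelfs)
```

## The problem

Serum protein microarrays measure the reactivity of thousands of protein
antigens per sample. In a case/control design — here Alzheimer's disease
(AD) versus healthy controls — the analytical task is to find a *small*
panel of markers whose joint expression separates the two groups, and then
to quantify how well that panel holds up under resampling, in an
independently collected cohort, and region by region in brain expression
data. `panelfs` implements this pipeline end to end, with a synthetic
cohort generator that reproduces the statistical structure the analysis
relies on, so that every stage can be exercised and tested without any
external download.

## The classifier and its score

All stages share one fixed classifier configuration (`svm_spec()`): a
C-classification support vector machine with radial-basis kernel
$K(u,v) = \exp(-\gamma \lVert u-v \rVert^2)$, cost $C = 1$, and
$\gamma = 1/p$ where $p$ is the number of features of the panel being
trained. Features are standardized by the *training-set* mean and standard
deviation; a zero-variance feature gets unit scale rather than a division
by zero. These are the de-facto defaults of the standard libsvm interface
in R, inherited silently by most applied work, so reproducing them exactly
matters more than tuning them. A configuration flag disables the
standardization for sensitivity analyses.

The evaluation score of a feature set is its leave-one-out
cross-validation (LOOCV) accuracy (`loocv_accuracy()`): each sample in
turn is predicted by a model trained on the remaining $n-1$. Two details
are deliberate:

* $\gamma$ is re-resolved per candidate panel ($1/|\text{panel}|$), since
  the "one over the feature count" rule is panel-relative;
* standardization statistics are recomputed inside every fold from that
  fold's training samples only. Computing them once on the full data would
  leak the held-out sample into the transform and bias the score upward.

LOOCV is deterministic given the data, so selection is exactly
reproducible.

The radial kernel is not incidental. A recurring single-marker pattern in
this setting is the *banded* distribution: healthy values occupy an
interval while disease values fall beyond it on *both* flanks, so the
normal range has an upper and a lower limit. A linear score with one
threshold cannot exceed majority-flank accuracy on such a marker, whereas
the radial kernel carves out the healthy interval directly. `fit_banded()`
quantifies this per marker by exhaustively searching all two-threshold
interval rules (cut points at midpoints of sorted distinct values, plus
infinite bounds, ties resolved toward the widest interval) and comparing
the best interval accuracy against the best single-threshold accuracy; a
marker is flagged banded when the interval wins by more than a margin
(default 0.05). The interval family contains every single-threshold rule
(one bound at infinity), so the interval accuracy can never be lower.

## Preprocessing

`floor_log_transform()` sets values below one to one and applies log2, so
transformed values are non-negative and the sub-unit tail of array
intensities maps to zero. Age and gender are then removed feature by
feature (`fit_robust_correction()` / `apply_correction()`): a Huber
M-estimator linear regression (IRLS, tuning constant 1.345, MAD scale,
at most 50 iterations) of log2 expression on age (years) and a 0/1 gender
indicator (reference level first alphabetically), fitted over all samples
with complete covariates in both diagnosis groups jointly. The corrected
value is the intercept plus the residual, i.e. the observed value minus
the fitted covariate contributions — which preserves each feature's
location and residual ordering. Robust regression is used because single
gross array artifacts should not tilt a feature's age slope; the test
suite checks that one +10 log2-unit outlier moves the Huber slope by less
than a fifth of what it does to least squares.

Degenerate cases are passed through rather than dropped: features whose
IRLS fails (or whose design is degenerate — constant age *and* a single
gender) keep their observed values and are flagged `converged = FALSE`;
samples with missing covariates keep observed values and are counted in a
message. The default pipeline corrects after restricting to the AD and
control samples; a configuration flag swaps that order for cohorts where
the correction should see all diagnoses.

## The two selection algorithms

Both algorithms are greedy forward searches embedded in the fixed SVM and
scored by LOOCV; they differ only in how the next candidate is chosen.

**SVMFS** (`svmfs()`) starts from the single feature with the highest
LOOCV accuracy. At each round it evaluates the current panel extended by
*every* remaining feature and takes the best-scoring extension. **SVMTFS**
(`svmtfs()`) ranks all features once by single-feature LOOCV accuracy and
considers candidates strictly in that order — the candidate at round $k$
is the $k$-th ranked feature, independent of the current panel, making it
roughly $p$ times cheaper per round.

The continuation rule is shared: a candidate is included only if it
improves the score by strictly more than a threshold, zero by default — a
feature that merely ties is rejected and the search stops
(`terminated_reason = "no_improvement"`; exhaustion of the pool and an
optional panel-size cap are the other exits). With the zero threshold,
panels stop naturally at two or three features on both the real and the
synthetic cohorts. Ties between equally good candidates go to the lowest
original column index, and duplicated columns can never follow their twin
into the panel (a duplicate adds no information, so its improvement is
never strictly positive) — both facts are asserted as invariants in the
tests. For SVMTFS the stop-on-non-improvement reading of the rule is the
default; a `skip_nonimproving` flag tries the next ranked candidate
instead, for users who read the pre-ranked variant as a filter rather
than a stopping rule.

The selection LOOCV is computed on the full discovery cohort, which is the
classical wrapper-selection design and embeds the selection optimism that
the cross-cohort stage is meant to expose; a nested cross-validation that
removes this bias is deliberately out of scope.

`svmfs()`/`svmtfs()` return a `selection_trace` — the ordered features
with the score after each inclusion — with `print`, `summary`, `coef`,
`plot`, `as.data.frame` and `predict` methods (the trace carries a final
SVM trained on the whole cohort with the selected panel).

## Evaluating a panel

`metrics_from_counts()` derives the panel of confusion metrics:
sensitivity, specificity, PPV, NPV, FDR $= 1 - \mathrm{PPV}$, FOR
$= 1 - \mathrm{NPV}$ and accuracy. FDR and FOR here are confusion-matrix
complements — the error rates among positive and negative *calls* — not
multiple-testing quantities. A ratio with a zero denominator is `NA`,
excluded from averages and counted, rather than silently coerced to zero.

`repeated_split_cv()` repeats a stratified random split many times
(defaults mirror the discovery design: 30 AD + 30 healthy drawn without
replacement for training, the remainder for testing, 5000 repeats;
the validation-cohort design uses 20 + 20). Each repeat contributes the
full metric panel plus an AUC from the decision scores; means are taken
per metric over the repeats where it is defined. Repeat $i$ draws its
random numbers from substream `seed + i`, so enlarging the repeat count
extends — never reshuffles — the earlier repeats, and identical seeds give
byte-identical per-repeat tables.

`roc_auc()` computes AUC as the Mann–Whitney rank statistic (tied pairs
count one half) and emits ROC points at every distinct threshold; the
trapezoidal area under those points equals the rank statistic to
$10^{-12}$, which the tests assert, and the result matches both
brute-force pair counting and an established ROC implementation.

`cross_cohort_validate()` trains once on the full discovery cohort and
predicts every sample of an independent cohort. Panel features are matched
in the test cohort by gene symbol first — so an RNA cohort on a different
platform can serve as the validation set — and by probe id second.
`grouped_loocv()` runs the LOOCV independently inside each level of a
grouping field (e.g. six brain regions), skipping groups with fewer than
two samples in either class instead of failing. `panel_correlations()`
reports pairwise Pearson correlations overall and within each diagnosis
class, where the strong co-banding of flank membership across markers
shows up as $|r|$ near 1 in the disease group.

## The synthetic cohorts

`synthetic_spec()` fixes the generative model; its defaults are the study
conditions used throughout the tests.

* **Cohort shapes.** 50 AD + 40 healthy in discovery; 36 AD + 57 healthy
  in the validation cohort; ages uniform on 60–90 years; genders balanced.
* **Banded markers** (two by default). Healthy values are normal around
  the band centre with sd 0.33 log2 units inside a half-width-1 band
  (≈ 99.8% inside). Each AD sample carries a latent flank variable
  $F \in \{-1, +1\}$ *shared across markers*; marker $m$ places the
  sample at $\text{centre} \pm (\text{half-width} + \text{gap})$ on the
  flank given by $F$ and the marker's loading sign, plus marker-specific
  noise. Sharing $F$ is the point: it makes flank membership co-occur
  across markers, which is exactly the mechanism behind the near-unit
  disease-group correlations between banded markers.
* **Correlation targets.** The marker-specific noise sd is derived from a
  single-factor decomposition of the target correlations, so the
  population disease-group correlation of a pair equals its target
  exactly (the closed form used as the oracle in the tests). The default
  two-marker target is $r = 0.99$; a three-marker geometry with the
  signed pattern $(0.99, -0.95, -0.94)$ is supported, with loadings
  clamped at 0.9999 where the triple is not jointly attainable by one
  factor. With the default flank gap of 0.3, the implied flank noise
  (sd ≈ 0.13) leaves roughly 1% of disease values inside the normal band
  — so single markers score LOOCV ≈ 0.96–0.99 rather than a degenerate
  1.0, different markers miss *different* samples, and panels genuinely
  improve on singles.
* **One-sided marker.** One classic shifted marker (effect 1.5 log2
  units, sd 0.5, Bayes error ≈ 7%) populates the mid-range of the
  single-feature ranking.
* **Background.** 200 uninformative features, class-independent normal in
  log2 space with means uniform on 0–8; the low end puts ≈ 5% of raw
  values below one, exercising the floor rule.
* **Confounding.** Per-feature age and gender coefficients are drawn with
  sds 0.01 log2/year and 0.1 log2; the correction stage is expected to
  remove them, and a loop-closure test checks the post-correction
  age correlation of the most confounded (unfloored) features is below
  0.05.
* **Second cohort.** The validation cohort is drawn from the same process
  with a location/scale perturbation applied to all features in log2
  space (default: +1 log2 unit), emulating cohorts normalized by
  different procedures. At zero shift the two cohorts are exchangeable
  draws (checked by Kolmogorov–Smirnov on pooled centred noise values).
* **Grouped cohort.** Six blocks of 15 AD + 12 healthy by default, with
  the planted effects confined to designated signal groups.

What the generator does *not* emulate: spot-level array artifacts,
autoantibody chemistry, platform-specific normalization, or correlated
noise among background features (independence is assumed). Passing tests
therefore demonstrate that the algorithms behave correctly on data with
the assumed structure — planted markers, known confounding, a controlled
cohort shift — not that any particular biological cohort will yield
panels of the same quality.

## Numerical choices and degenerate inputs

* Strict inequality in the selection continuation rule; at threshold zero
  a zero-improvement candidate terminates (or is skipped in skip mode).
* Selection ties break toward the lowest original column index; banded
  interval ties toward the widest interval; single-feature ranking is a
  stable sort.
* IRLS: Huber $k = 1.345$, MAD scale, convergence tolerance $10^{-8}$,
  50-iteration cap; non-converged features pass through flagged.
* Zero-variance features under standardization get scale 1 and are
  logged; a constant feature yields LOOCV at or below the majority rate
  and is an error for the banded fit.
* Decision scores are oriented so that larger means more disease-like,
  independent of the engine's internal label order; exact zero decisions
  resolve to the engine's second label, matching its own predictor.
* Matrix values are serialized with 17 significant digits, so a
  write/read round trip is bit-exact.

## Problem sizes used in the checks

The bundled tests and the acceptance script run the full pipeline at the
default study conditions: 203 features (2 banded + 1 one-sided + 200
noise) by 90 samples for selection, 5000-repeat resampling for the metric
battery, 20 generator seeds for the recovery and correlation properties,
and an 8-seed average over a four-point shift grid for the cross-cohort
degradation trend. These sizes were chosen as the smallest at which the
Monte-Carlo noise of each property is comfortably below the asserted
margins.

## Known limitations

* The wrapper selection's LOOCV is optimistically biased by design; treat
  discovery scores as selection scores, not generalization estimates —
  the cross-cohort stage exists to make that gap visible.
* Cross-cohort degradation under the location shift is not guaranteed to
  be pointwise monotone: with a radial kernel, intermediate shifts can
  move one flank of the disease distribution *into* the learned healthy
  region, producing locally non-monotone AUC. The coarse-grid trend
  (larger shift, no better transfer) is the property that holds and is
  tested.
* Group labels, cohort labels and gene symbols are matched as plain
  strings; no identifier harmonization beyond upper-casing of gene
  symbols is attempted.
* The banded-fit search is $O(k^2)$ in the number of distinct values —
  fine for cohort-sized vectors, not meant for tens of thousands of
  samples.
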