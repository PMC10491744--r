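---
title: "Connectome-based predictive modeling of mood severity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modeling of mood severity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodcpm)
```

## The modeling problem

Connectome-based predictive modeling (CPM) asks whether a clinical score —
here the severity of depressed mood (HDRS-5, the sum of the five Hamilton
Depression Rating Scale items loading most on depression) or of elevated
mood (the 11-item Young Mania Rating Scale total) — can be predicted, one
held-out person at a time, from that person's functional connectome. The
connectome is a symmetric node × node matrix of Fisher-z-transformed
Pearson correlations between regional fMRI time courses, over a 368-node
whole-brain atlas (cortex, subcortex, cerebellum, brainstem; each node
assigned to one of ten bilateral macroscale regions). Only the
`n(n-1)/2 = 67,528` unique edges enter the analysis; the diagonal is
undefined.

The procedure, per leave-one-out fold:

1. **Edge selection.** Each edge is correlated with the clinical score
   across the training subjects; edges with a two-tailed `p < 0.001`
   (strict) form the *positive* network if `r > 0` and the *negative*
   network if `r < 0`.
2. **Network strength.** Each training subject's selected edge weights are
   summed, separately per sign, giving two scalar strengths.
3. **Linear model.** Ordinary least squares relates strength to score:
   one slope + intercept for the single-network models, and a bivariate
   fit on (positive strength, negative strength) for the combined model.
4. **Prediction.** The held-out subject's strengths, computed with the
   fold's masks, are pushed through the fold's coefficients.

Concordance between predicted and observed scores (Pearson r) and RMSE
summarize performance over all folds. Edges selected in *every* fold — the
consensus masks — are the interpretable predictive networks: their node
degrees identify hub nodes, and each edge is classified as
inter-hemispheric, intra-left, intra-right, or midline-involving, with its
unordered macroscale region pair.

Because LOOCV folds share `n - 2` subjects, parametric p-values for the
concordance overstate the degrees of freedom. Inference is therefore by
permutation: the score-connectome correspondence is shuffled (covariates
stay attached to their subjects) and the *entire* pipeline — selection and
fitting inside every fold — is rerun per shuffle (5000 by default).

## Numerical and design choices

Several points are deliberately pinned down where the protocol leaves room:

* **Fisher transform at |r| = 1.** Node time courses that are exactly
  (anti-)proportional give `r = ±1`; r is clamped to `±(1 - 1e-7)` before
  `atanh`, keeping edge weights finite without materially changing sums.
* **Edge ordering.** Edge vectors use the row-major upper triangle
  (`(1,2), (1,3), …`), 1-based in every file format; `vectorize_edges()` /
  `devectorize_edges()` round-trip bit-for-bit.
* **Strict threshold.** Selection uses `p < alpha` strictly; an edge at
  exactly `p = 0.001` is excluded. Inside the LOOCV engine the equivalent
  critical-r² form is used (`p < alpha ⇔ r² > t²/(df + t²)`, same strict
  inequality), which avoids per-edge CDF evaluations without changing any
  decision.
* **Degenerate edges and folds.** A numerically constant edge gets
  `(r, p) = (0, 1)` and can never be selected. A fold whose mask is empty
  predicts the training mean — the limit of the strength fit when a
  regressor has zero variance (slope 0, absorbed into the intercept). If
  *all* predictions are constant, concordance r is defined as 0; the rule
  applies identically to observed and permuted runs, so permutation
  calibration is unaffected.
* **Combined model.** A bivariate least-squares fit on both strengths
  (two slopes + intercept), nesting both single-network models; collinear
  strengths fall back to the positive-strength fit. The alternative —
  summing strengths before a univariate fit — is not the default.
* **Consensus.** Full intersection over all folds, a literal reading of
  "edges common to every iteration".
* **Permutation p.** The add-one convention
  `p = (1 + #[null r ≥ observed r]) / (n_perm + 1)`, with ties counted
  (conservative); the raw proportion is also reported. The fold order is
  the subject order; the only randomness anywhere is the shuffle sequence,
  fixed by the seed.
* **No leakage, exactly.** Per-fold edge statistics are assembled from
  column sums of the full edge matrix (which do not involve the scores)
  plus one matrix product against score vectors with the held-out entry
  zeroed. Nothing is "subtracted back", so perturbing a held-out subject's
  score leaves its fold's masks and prediction identical to the last bit —
  a property the test suite asserts literally.
* **Outlier QC.** The exclusion criterion for aberrant connectomes is not
  part of the published protocol; the package adopts a declared,
  reproducible substitute: each subject's edge vector is correlated with
  the leave-one-out median connectome, and scores below `Q1 − 1.5·IQR` are
  flagged (reported, never silently dropped). The leave-one-out medians
  come from per-edge order statistics, so QC is exact and fast at the full
  368-node scale.
* **Missing scores.** Per-target complete-case exclusion, mirroring how a
  validation roster with missing mania scores is reduced (43 → 41); no
  imputation.
* **High-degree nodes.** "Hub" has no numeric definition in the protocol;
  `top_nodes()` takes the top k (default 2, the number typically narrated
  per network) with ties at the cutoff rank expanded and logged.
* **Transfer.** `apply_trained_model()` uses the frozen masks and
  coefficients only — no re-selection, no re-fitting — and refuses cohorts
  overlapping the training roster. Both plain and covariate-adjusted
  (age, gender) concordances are reported, since the published transfer
  statistics are ambiguous between the two.

## What the synthetic cohorts emulate

The clinical fMRI data behind the original analysis are not deposited, so
`generate_cohort()` provides the test bed. Per subject it draws a latent
clinical score, builds an edge vector as a shared group-mean connectome
(`N(0.25, 0.3)` across edges, Fisher-z units) plus subject noise
(SD 0.2), and adds `±β·z` to the planted positive/negative edges, where
`z` is the score standardized by its realized sample moments and
`β = effect_r/√(1−effect_r²) × noise SD`, so a planted edge's population
correlation with the score is the configured `effect_r`. Defaults are the
study conditions: 81 training subjects, 368 nodes, 40 + 40 planted edges
concentrated on two hub nodes per sign with probability 0.5, per-edge
`effect_r = 0.5`; validation cohorts reuse the training ground truth
(masks and group-mean connectome) with fresh subjects, a distinct id
prefix, and per-subject noise-scale variation (0.8–1.3) standing in for
heterogeneous acquisition.

Scores are truncated-rounded normals matched to the published scale
moments (HDRS-5 3.4 ± 3.4 on 0–13; YMRS 6.5 ± 6.1 on 0–23; HDRS-29
12.3 ± 10.1 on 0–40). Two caveats are worth stating plainly. First,
real rating-scale distributions are zero-inflated and right-skewed; their
printed mean/SD pairs sit slightly outside what any truncated normal can
attain (e.g. on [0, 13] a mean of 3.4 caps the SD near 3.0, and an SD of
11.1 on [18, 55] exceeds the uniform limit for age). The generator fits
the closest family member by least squares on the analytic truncated
moments, which lands within a few tenths of the targets. Second, the
effect is injected linearly in the standardized score, matching the linear
model's assumption — parameter-recovery results therefore test the
implementation, not robustness to misspecification (a quadratic-injection
switch exists for that, off by default). Covariates (age ~29.3 on 18–55,
63% female, mean framewise displacement < 0.2 mm) are independent of the
connectome unless the age-confounding switch is on. None of this models
hemodynamics, task structure, or scanner effects beyond noise scale; a
passing suite says the *pipeline* is correct under its own assumptions,
not that real fMRI would yield these effect sizes.

## Problem sizes and runtime choices

The test suite and the analysis scripts choose sizes that keep a full run
on one CPU comfortable while preserving the statistical structure:
permutation calibration uses 100 null cohorts of 40 subjects over a
60-node atlas with 200 shuffles each (the rejection rate at 0.05 must sit
inside the exact binomial 95% interval); parameter recovery uses 20 seeds
of 150 subjects over 120 nodes with 40 + 40 planted edges at per-edge
r ≈ 0.6 (consensus sensitivity ≥ 0.9, false-discovery proportion ≤ 0.1,
and permutation significance in ≥ 95% of seeds); the exhaustive
permutation check enumerates all 120 orderings of a 5-subject cohort
against a naive reference implementation. The analysis scripts and the
acceptance script run at the full study scale (81 + 43 subjects, 368
nodes) with 1000 shuffles; increase `n_perm` to 5000 for
publication-grade p resolution at a proportional runtime cost.

## Worked example

```{r example, eval = FALSE}
library(moodcpm)

g  <- generate_cohort(sim_config(seed = 11, n_outliers = 1))
qc <- flag_outlier_subjects(g$cohort$edges)
cohort <- subset_cohort(g$cohort, qc$subject_id[!qc$flag])

cv <- run_loocv(cohort, "hdrs5")           # LOOCV at alpha = 0.001
pt <- permutation_test(cohort, "hdrs5", n_perm = 1000, seed = 202)

deg <- node_degrees(cv$consensus$neg, default_atlas())
top_nodes(deg, 2)                          # hubs of the negative network

model <- train_cpm(cohort, "hdrs5")        # frozen, transferable artifact
gv <- generate_cohort(sim_config(n_subjects = 43, id_prefix = "V",
                                 noise_scale_range = c(0.8, 1.3),
                                 seed = 12), truth = g$truth)
pred <- apply_trained_model(model, gv$cohort)
evaluate_transfer(pred[, "combined"], gv$cohort$scores$hdrs5,
                  gv$cohort$covariates[, c("age", "gender")])
```

The `analysis/` directory walks through the same pipeline as five
narrative scripts (simulate + QC, LOOCV, permutation inference, network
interpretation, external validation), writing small TSV/JSON outputs under
`results/`.

## Known limitations

* Planted effects at the default per-edge correlations (0.5–0.6) produce
  much higher concordances than real clinical fMRI (r ≈ 0.2–0.5); the
  synthetic results validate mechanics, not expected field performance.
* The truncated-normal score family cannot reproduce the zero-inflation of
  real rating scales (see above).
* Only leave-one-out cross-validation is implemented; k-fold and
  split-half variants, regularized models, and harmonization across
  scanners are out of scope.
* The outlier fence is a package convention, not the original study's
  (unstated) criterion; at tight fences on left-skewed correlation scores
  an occasional non-planted subject can be flagged.
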