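---
title: "Multivoxel pattern analysis of FDG-PET metabolism: models and methods"
author: "petmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivoxel pattern analysis of FDG-PET metabolism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmvpa)
```

# The problem

Resting-state FDG-PET measures regional cerebral glucose metabolism, a
proxy for neural activity.  Group differences in metabolism are often
subtle and spatially distributed: a treatment may lower metabolism by a
few percent across a network of regions while sparing others, and
between-subject nuisance variation (global tracer dose, age-related
decline) is larger than the effect of interest.  Mass-univariate
voxelwise testing has little power in this regime.  Multivoxel pattern
analysis (MVPA) instead asks whether the *joint* spatial pattern of
metabolism discriminates the groups, and then reads the learned pattern
back as a pair of candidate networks.

`petmvpa` implements that full analysis for a two-group design — treated
("CHT") versus untreated ("NOCHT") subjects — together with a synthetic
phantom generator, so every stage is testable without access to patient
scans.

# The analysis pipeline

1. **Smoothing.** Each volume is blurred with an isotropic Gaussian
   kernel (default FWHM 12 mm; sigma = FWHM / (2 sqrt(2 ln 2))), applied
   separably per axis with reflect boundary handling.
2. **Reference-region normalization.** Every voxel is divided by the
   mean count of a pontine-style reference box (default: the open box
   −8 < x < 8, −16 < y < −8, −34 < z < −24 mm; a voxel counts as inside
   when its *center* falls strictly inside all three open intervals).
   This removes global scale differences between subjects; the output's
   reference mean is 1 by construction, and the operation is idempotent
   and invariant to a global rescaling of the input.
3. **Linear nu-SVM.** Every brain-mask voxel is a feature; a linear
   nu-SVM learns the separating hyperplane w·v + b = 0.  The explicit
   weight map is recovered from the support-vector expansion
   (w = Σ α_i y_i v_i, b = −rho) and re-oriented so a positive decision
   value means "untreated".  Accuracy is estimated by leave-pair-out
   cross-validation: each fold holds out one subject per group, drawn as
   a seeded random partition so every subject is held out exactly once
   (14 folds at n = 28).  An optional grid search selects nu by the same
   cross-validation (ties toward the smaller nu).
4. **Signed patterns.** "Weights well above zero" is operationalized as
   a percentile of |w| over the brain mask (default p = 90; percentiles
   are scale-free under feature rescaling).  Voxels with w ≥ +threshold
   form the positive pattern, w ≤ −threshold the negative pattern.
5. **Network means.** For each subject, the mean normalized metabolism
   over each pattern gives two scalars per subject (called `pcs_mean`
   for the positive and `dan_mean` for the negative pattern).  Which
   sign corresponds to the clinically interpretable hypometabolic
   network is decided *post hoc* — by which side actually shows the
   group difference — and reported, never assumed from the label coding.
6. **Cut-off models.** Subjects are classified from the network means
   alone: the best single threshold per network (exhaustive search over
   the n + 1 midpoints of the sorted values, both orientations), and the
   best "floating cut-off" — a line PCS = intercept + slope · DAN in
   (DAN, PCS) space.  The line search is exact: every combinatorially
   distinct slope (defined by a pair of subjects, plus the horizontal
   and vertical directions) is combined with an exact 1D threshold
   search on the projection pcs − slope·dan.  The family nests all
   single cut-offs, so its training accuracy can never be lower.  Both
   in-sample and leave-pair-out cross-validated accuracies are reported,
   clearly labeled, because they answer different questions.
7. **Group statistics.** Pooled-variance two-sample t tests, the
   uncorrected 2×2 Pearson chi-square, Pearson correlations, Kendall
   tau-b (tie-corrected, normal-approximation p), and ANCOVA
   (dependent ~ group + covariate, no interaction) support the group
   comparisons.

## Why the floating cut-off works

The mechanism the two-feature model exploits is nuisance cancellation.
Both network means ride on the same subject-level factors (age-driven
decline, residual global scale), so they are strongly positively
correlated across subjects.  The treatment effect, however, loads on
only one of them.  A single PCS threshold confounds "low because
treated" with "low because older"; the DAN mean is an internal reference
for what the PCS mean *should* be at that subject's age, so a threshold
on PCS *relative to DAN* — a line in (DAN, PCS) space — removes the
shared variance and isolates the treatment effect.  On the synthetic
cohorts this is visible directly: the floating model's cross-validated
accuracy exceeds the single-PCS model's in almost every seed.

# The synthetic phantom

The generator plants exactly the structure the analysis is designed to
detect, with defaults chosen as the package's reference study
conditions:

* **Grid**: 48 × 56 × 44 voxels of 2 mm (a whole-head field of view);
  the brain is an ellipsoid with semi-axes 45% of the grid extent.
* **Cohort**: 14 subjects per group; ages drawn uniformly over 35–69
  years for one group and mirrored into the other, so the groups are
  exactly age-matched (mean 52, SD ≈ 10); gender 12 M / 2 F in both
  groups, assigned deterministically; depression scores ~ round
  N(4, 3²) clamped to 0–21; months since treatment ~ gamma with mean 7
  and SD 9 (treated subjects only).
* **Networks**: PCS = bilateral prefrontal spheres (r = 12 mm) plus
  posterior-inferior cerebellar spheres (r = 10 mm); DAN = bilateral
  superior-parietal (r = 11 mm) plus dorsal-frontal (r = 9 mm) spheres;
  all mirrored across the midsagittal plane, clipped to the brain,
  mutually disjoint.  The reference box (16 × 8 × 10 mm, 160 voxels at
  2 mm) sits central-inferior, inside the brain but outside both
  networks.
* **Signal model**: voxel = baseline · g(age) · (1 − 0.10 · [CHT] ·
  [voxel ∈ PCS]) + noise, with baseline 100 counts, g(age) = 1 +
  slope · (age − 52), slope −0.8%/year in background tissue and
  −0.8% · 1.75 per year inside the two networks, additive Gaussian noise
  with SD 5% of baseline inside the brain, then a 6 mm FWHM
  point-spread blur.  Blur is applied after noise so the noise is
  spatially correlated, as in reconstructed PET.  The reference region
  receives neither the age nor the group modulation — a deliberate
  idealization that makes normalization unbiased.

Two generator choices deserve their rationale:

* **Network age gain (1.75).**  Real resting-state networks covary
  strongly across subjects relative to background tissue — empirically,
  the two extracted network means correlate around 0.8 with each other
  and around −0.5 with age.  If the age factor were spatially uniform,
  the SVM's nuisance-cancelling negative weights would spread thinly
  over the whole brain and no concentrated negative (DAN-like) pattern
  would survive percentile thresholding; amplifying the networks' age
  sensitivity reproduces the observed covariance structure and
  concentrates the cancellation on DAN.  The value 1.75 was calibrated
  once against the package's property suite (all of: PCS group t test
  significant and DAN t test non-significant in ≥ 8/10 seeds; Dice
  between extracted and planted PCS ≥ 0.5; floating cut-off beating the
  single cut-off in ≥ 7/10 seeds) and is not revisited.
* **Multiplicative effects.** PET counts are scale-valued, and the
  downstream normalization is a ratio; multiplicative group and age
  effects survive it with clean interpretation (a 10% planted reduction
  stays a 10% reduction of the normalized mean).

What the phantom deliberately does **not** model: real anatomy,
attenuation and scatter, partial-volume effects, scanner-specific
reconstruction, registration error, or any correlation between the
covariates and the planted networks beyond age.  Passing tests
demonstrate that the *pipeline* recovers planted structure under
PET-like noise and blur — not that any particular clinical effect
exists, nor how large it is in patients.

# Numerical and design choices

* **Gram-factor cross-validation.** With tens of thousands of voxel
  features and 28 subjects, every linear-SVM dual depends on the data
  only through the 28 × 28 Gram matrix.  Cross-validation therefore
  trains each fold on an exact eigen-factor Z of X Xᵀ (Z Zᵀ = X Xᵀ),
  which leaves every dual solution and every prediction unchanged
  (asserted against direct training in the test suite) while making
  fold training essentially free.  The final weight map is always
  trained on the full voxel matrix.
* **Tie rules.** A decision value of exactly zero classifies as
  untreated (+1); cut-off boundary points resolve to the untreated
  side; single-threshold ties break toward the widest flanking gap,
  then the lowest threshold; line-search ties toward the widest
  geometric margin, then the smaller |slope| (axis-aligned lines
  preferred).  All are documented and tested.
* **Degenerate inputs.** Constant values with mixed labels return the
  majority-class accuracy with a `degenerate` flag; an all-zero weight
  map, an empty pattern side, an empty mask, a reference ROI that
  misses the grid, a non-positive reference mean, single-class training
  data and infeasible nu all raise explicit, distinguishable errors.
* **Zero-variance t tests** follow printed-table conventions: p = 1
  when the means are equal, p = 0 otherwise, so exactly balanced group
  summaries reproduce p = 1.00 rows.  The chi-square uses no continuity
  correction (the corrected statistic would not reproduce the reference
  table's p = 0.01 localization row); a zero marginal gives statistic 0,
  p = 1.
* **Smoothing boundary**: reflect (edge-repeating mirror), which
  preserves constants and avoids edge dimming on small grids; kernels
  are sampled Gaussians truncated at 4 sigma and renormalized.
* **Pipeline order** is fixed as smooth → normalize; the normalization
  constant is taken from the smoothed image.
* **Calibration checks.** The type-I-error suite evaluates the t test
  at the study's own size (two groups of 14) and the chi-square at two
  binomial(30, 0.4) groups.  The uncorrected chi-square is genuinely
  conservative at 14 per group (discreteness), so its calibration is
  checked at a size where the chi-square approximation to the Pearson
  statistic is accurate; this is a check of the implementation, not of
  small-sample exactness.

## Problem sizes used by the test and acceptance suites

Unit tests run the same template geometry on a coarser 3 mm grid
(32 × 38 × 30 voxels); property suites run 10 seeded cohorts at the full
default conditions; oracle-equivalence suites use 100 random datasets
(single threshold) and dense 1000 × 1000 grid comparisons on datasets of
n ≤ 12 (floating line); the calibration suite uses 2000 null
simulations.  The 10-seed property loops train at the fixed default
nu = 0.5; the grid search over nu ∈ {0.1, …, 0.9} is exercised
separately and in the acceptance pipeline.

# Known limitations

* The phantom's networks are geometric sphere unions, not anatomical
  networks; Dice scores against them say nothing about anatomical
  localization accuracy in real data.
* The leave-pair-out partition estimates accuracy with high variance at
  n = 28; the permutation null, not a fixed "chance > 57%" rule, is the
  package's reference for significance of an observed accuracy.
* In-sample cut-off accuracies are optimistically biased (the threshold
  is chosen on the same data); they are reported alongside the
  cross-validated accuracies because published analyses of this design
  typically quote the in-sample figure.
* Extracting network means from patterns selected on the same cohort is
  circular; the group t tests on those means are descriptive of the
  training cohort, and only the cross-validated accuracies carry
  out-of-sample meaning.

# A minimal run

```{r, eval = FALSE}
cfg <- pipelineConfig(seed = 1, outputDir = "petmvpa_run")
res <- runPipeline(cfg)
str(res$summary)
```

The summary reports the cross-validated SVM accuracy, the two network
group p values, the three cut-off accuracies (in-sample and
cross-validated), the Dice overlap between the extracted and planted
PCS, the network correlations, and the age-adjusted ANCOVA — the same
quantities `scripts/acceptance.R` recomputes from scratch.
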