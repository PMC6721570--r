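---
title: "Methods: radiomic and multi-omic survival modelling in radsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic and multi-omic survival modelling in radsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(radsurv)
```

`radsurv` implements a survival-prediction pipeline for IDH1 wild-type
glioblastoma that integrates 3D radiomic features of the
contrast-enhancing tumor with genomic, transcriptomic, protein and
clinical variables. This vignette is the package's own account of the
methods: the models, the conventions chosen where several are defensible,
the synthetic validation cohorts, and the limits of what the tests show.

## Image preprocessing

Multi-site MR data arrive at heterogeneous voxel sizes and intensity
scales, so texture statistics are only comparable after harmonization:

* **Isotropic resampling to 1 mm** (`resample_isotropic()`): trilinear
  interpolation for images, nearest-neighbour for masks (preserving
  binarity). The output grid has `round(dim * spacing)` voxels per axis,
  centres aligned with the first input voxel centre. No fixed in-plane
  matrix (such as 256 × 256) is enforced — only a shared grid between
  volume and mask matters for the feature mathematics.
* **Per-volume min–max normalization** (`normalize_intensity()`):
  `(x − min)/(max − min)` over the whole volume. A constant volume maps
  to zeros — a defined, testable convention that avoids division by
  zero.
* **Gray-level quantization** (`quantize_gray_levels()`, Ng = 32):
  uniform binning of *in-mask* intensities between the in-mask minimum
  and maximum, `level = 1 + floor(Ng (x − min)/(max − min))` with the
  maximum clipped into bin Ng. ROI-relative binning (rather than a fixed
  [0, 1] range) is the dominant convention for these descriptors; a
  constant ROI maps to level 1 everywhere.

## The 45-feature roster

The signature comprises 4 shape + 6 intensity + 19 GLCM + 11 GLSZM + 5
NGTDM = 45 features (`radiomic_feature_names()`). The roster is a
documented reconstruction: it uses the standard member sets of the three
texture families plus the classical shape and histogram descriptors, and
includes every feature the source analyses single out by name
(sum-of-squares variance, autocorrelation, small-zone/high-gray
emphasis, large-zone/low-gray emphasis). Conventions that matter:

* **GLCM**: co-occurrences at distance 1 are accumulated over all 13
  unique 3D directions into a single matrix (rotation-robust, the common
  choice over per-direction averaging), counting only pairs with both
  voxels in the mask, each pair in both orders (symmetric). Logarithms
  are base 2 with 0·log 0 = 0; correlation and the first informational
  measure are defined as 0 when a marginal variance vanishes.
* **GLSZM**: zones are maximal 26-connected components of equal gray
  level. Mass conservation (Σ j·s(i,j) = in-mask voxel count) holds by
  construction and is asserted in tests.
* **NGTDM**: a voxel contributes only if every in-grid 26-neighbour
  position is inside the mask (the classical complete-neighbourhood rule
  extended to masks); the neighbourhood mean is taken over those
  neighbours. Coarseness is 1/(1e−6 + Σ pᵢsᵢ) capped at 1e6, so a
  homogeneous ROI yields a finite, testable value.
* **Shape**: surface area by boundary-face counting; fractal dimension
  as the least-squares log–log slope of box counts over dyadic box sizes
  {1, 2, 4, 8, 16} on the cropped bounding box; porosity as the voxel
  fraction of internal cavities after 6-connected hole-filling — the
  cited literature gives no formula, so this ratio is the package's
  definition.

Correctness is anchored two ways: hand-enumerated micro-examples
(e.g. GLCM autocorrelation 2.5 on a 2 × 2 worked ROI), and equivalence
with naive brute-force re-implementations (explicit per-voxel /
per-pair / per-zone loops) on dozens of random 8×8×8 ROIs to 1e−8.
IBSI-certified numerical compliance is explicitly not the bar; oracle
equivalence is.

## Univariate survival screen

Each feature is dichotomized at its sample median with ties going to the
"≥" group (anchored to the definition of long-term survival as at or
above the median OS). Groups are compared by the log-rank test and a
univariate Cox model (Breslow ties, Wald 95% CI) — Cox is the standard
generator of the reported HR + CI format. Log-rank p-values are
Holm–Bonferroni adjusted across the 45-feature family; degenerate
(constant) features are flagged rather than fatal, and excluded from the
correction family. Rank tests (Wilcoxon, Kruskal–Wallis) use exact
enumeration when the combined sample size is at most 10 — where
enumeration over midrank assignments is cheap even under ties — and the
tie-corrected normal/chi-square approximation otherwise; the 2 × 2
chi-square uses no continuity correction.

## Multivariate modelling

* **Censoring imputation**: a censored patient receives the mean
  survival of uncensored patients with time-to-death ≥ their last-visit
  time. A censored time beyond every uncensored time keeps its own value
  (the rule is undefined there); imputation therefore never decreases a
  time. An uncensored-only mode (drop censored, no imputation) is
  available as a sensitivity analysis.
* **Outcome**: median split of imputed OS — balanced classes by
  construction, avoiding class bias in training.
* **Random forest**: 500 trees, stratified 10-fold cross-validation
  (stratification prevents single-class folds at realistic cohort
  sizes; the source protocol says only "equal-sized subsets"). The
  headline metric is the mean of per-fold AUCs; the pooled out-of-fold
  AUC is reported alongside for transparency. Predicted short/long
  groups are out-of-fold probability ≥ 0.5, and are validated by
  Kaplan–Meier/log-rank on survival.
* **Permutation importance**: per tree, the out-of-bag error increase
  after permuting a feature; averaged over trees, divided by the
  standard deviation of tree-level increases (`randomForest`'s scaled
  importance), then averaged across the CV folds. Positive values mark
  predictive features.
* **Block integration**: column-wise concatenation over the patients
  shared by all requested blocks, with per-column block tags. The
  clinical block is age plus therapy type; categorical clinical
  variables are one-hot encoded (no encoding was specified at the
  source; indicators are the neutral choice for forests). Patients
  missing a block are dropped with a logged count.
* **Model comparison**: AUC differences between models are assessed by
  a chi-square test on the 2 × 2 table of correct/incorrect
  classification counts of the two models on the same patients — an
  operationalization chosen here, since the cited comparison method is
  not described in detail.

## Synthetic cohorts: what they emulate

The generator (`cohort_config()`, `generate_cohort()`) defines the
study conditions used throughout tests and the acceptance script:

* **Lesions**: ellipsoids (per-axis radii perturbed ±25%) centred in a
  32³ voxel, 1 mm grid; radius 6–10 mm. Interior texture is a Gaussian
  random field produced by FFT smoothing of white noise, with
  correlation length 1–6 mm per patient, rescaled into (0.1, 1];
  background is low-amplitude uniform noise. The correlation length is
  the texture dial: longer lengths mean smoother lesions, higher NGTDM
  coarseness and lower GLCM contrast. Because quantization is
  ROI-relative, this monotone link saturates once the correlation
  length approaches the lesion radius (a nearly-linear in-mask field
  rescales to the same gradient regardless of length) — the
  monotonicity test therefore operates within the generator's 1–6 mm
  range against ~10 mm lesions.
* **Survival**: exponential event times with hazard
  `baseline · exp(Σ βᵢ zᵢ)` over standardized feature columns — the
  simplest model matching proportional-hazards reporting, with
  analytically checkable parameter recovery. The baseline hazard
  (1/400 per day, null median OS ≈ 9 months) sits in the clinical range
  for IDH1 wild-type GBM. Censoring is an independent exponential whose
  rate is solved numerically (on the realized hazards) to hit the
  target censored fraction, 20% by default — keeping censoring
  non-informative, which is exactly the assumption of the imputation
  rule.
* **Omic blocks**: 100 binary mutation genes (population frequencies
  2–40%), 500 standard-normal expression genes, and a 6-protein IHC
  panel scored on the routine ordinal 0–3 scale then treated as numeric
  (no source scale is stated; 0–3 mirrors routine pathology scoring).
  Clinical covariates resemble an adult GBM cohort (age ~ N(61, 12²)
  clipped to 18–85, KPS 40–100, therapy RT+TMZ/RT/none at 70/20/10%).
* **Planted effects** name any generated feature column — including an
  extracted radiomic feature, so a planted radiomic effect propagates
  through the *actual* image → feature path, not a shortcut.
* **Determinism**: all randomness derives from the master seed (one
  derived seed per patient); regeneration is bit-identical, including
  the NIfTI files.

What the synthetic cohorts do *not* emulate: MR physics (bias fields,
noise spectra, partial volume), multi-sequence imaging, multifocal or
infiltrative lesion geometry, correlated gene networks, or
covariate-dependent censoring. Passing tests therefore demonstrate that
the pipeline recovers known signal and stays at chance under the null —
not that any particular AUC is attainable on patient data.

## Numerical and reporting choices

* Percentages in the demographics table are truncated (not rounded)
  toward zero at two decimals, reproducing the printed style of the
  reference cohort table (129/132 = 97.727 → 97.72).
* All entropies are base 2; ε = 1e−6 guards the coarseness and strength
  denominators.
* Cross-validated AUC under the null centres slightly below 0.5
  (≈ 0.46 at n = 200): a forest fitting pure noise produces weakly
  anti-predictive out-of-fold scores, a known property of CV on
  uninformative features — the chance band used in tests is 0.40–0.60.
* Problem sizes in tests and the acceptance script (200-patient
  cohorts on 32³ grids, 1000-record hazard recovery, 500 null log-rank
  replicates, 50 oracle ROIs at 8³) were chosen as the smallest sizes at
  which each statistical property is stable.

## Pipeline and provenance

`run_pipeline()` executes data acquisition (synthetic or from disk) →
preprocessing and extraction → univariate screen → transcriptome screen
(per-gene median-split log-rank at raw p < 0.05, mirroring a
pre-correction univariate gene panel) → block integration → outcome →
model → survival validation, logging every stage's input/output counts
so each patient is accounted for (used or dropped-with-reason). The
report JSON embeds the configuration hash, seeds and feature-roster
version, and reruns with the same configuration are byte-identical.
The numbered scripts under `analysis/` present the same workflow as a
narrative study; `scripts/acceptance.R` recomputes the verifiable
quantities from scratch.

## Known limitations

* The 45-feature roster is a reconstruction; other implementations'
  rosters (and IBSI definitions) differ in detail.
* Single-covariate Cox only; no multivariable survival regression or
  survival forests — the multivariate path is classification after
  median dichotomization, by design.
* Exponential survival makes planted log-hazard effects exactly
  recoverable but understates the heterogeneity of real OS
  distributions.
* The NGTDM complete-neighbourhood rule discards boundary voxels and so
  loses precision on very thin or small ROIs (a single-slice mask
  embedded in a 3D grid retains only interior in-plane voxels).
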