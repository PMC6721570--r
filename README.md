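# radsurv

Radiomic and multi-omic survival modelling for IDH1 wild-type
glioblastoma (GBM).

IDH1 wild-type GBM carries a dismal and variable prognosis, and single
molecular markers predict outcome poorly. `radsurv` implements, as a
tested and reusable R pipeline, an integrative analysis in which
quantitative imaging features of the contrast-enhancing tumor are
combined with mutation, expression, protein and clinical variables to
classify patients into short- versus long-term overall survival (OS).
It is aimed at imaging/biostatistics researchers who want every stage of
such an analysis — phantom simulation, feature extraction, univariate
screening, integration, modelling, reporting — as plain, testable
functions.

## What it computes

**45-feature 3D radiomic signature.** From an isotropically resampled
(1 mm), per-volume min–max normalized T1 volume and a binary tumor ROI,
quantized to Ng = 32 gray levels:

* 4 shape features (volume, surface area, box-counting fractal
  dimension, porosity via hole-filling);
* 6 intensity features (mean, variance, skewness, kurtosis, energy,
  32-bin Shannon entropy);
* 19 gray-level co-occurrence (GLCM) features from a single symmetric
  matrix summed over the 13 unique 3D directions at distance 1, e.g.
  autocorrelation = Σᵢⱼ i·j·p(i,j) and sum-of-squares variance
  = Σᵢⱼ (i − μₓ)² p(i,j);
* 11 gray-level size-zone (GLSZM) features over 26-connected equal-level
  zones, e.g. small-zone/high-gray emphasis = Σᵢⱼ s(i,j)·i²/j² / Nz;
* 5 neighbourhood gray-tone difference (NGTDM) features (coarseness,
  contrast, busyness, complexity, strength).

**Univariate screen.** Each feature is median-split; groups are compared
by Kaplan–Meier/log-rank and a univariate Cox hazard ratio (Breslow
ties, 95% Wald CI), with Holm–Bonferroni correction across the family.

**Multivariate models.** Censored times are imputed by the conditional
mean of uncensored times at least as large; patients are labelled
short/long-term at the median imputed OS; a 500-tree random forest is
evaluated by stratified 10-fold cross-validated AUC and by a 100/100
train/test split, with sd-normalized out-of-bag permutation importances
and log-rank validation of the predicted groups.

**Synthetic cohorts.** A seeded generator produces textured ellipsoidal
lesions (Gaussian-random-field interiors with controllable correlation
length) plus clinical/genomic/transcriptomic/protein tables whose
survival follows a proportional-hazards model with planted effects and
independent censoring — so every claim above is tested against planted
ground truth, without patient data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
200-patient synthetic cohort with a planted radiomic effect
(sum-of-squares variance, log-HR = log 3 per SD) and a planted mutation
effect (gene001, log-HR = log 2.5 per SD):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_extract_features.R
Rscript analysis/03_univariate_screen.R
Rscript analysis/04_multiomic_models.R
Rscript analysis/05_report.R
```

Output of the model stage (stage 4):

```
radiomics       mean 10-fold AUC = 0.777
radiomics_gen   mean 10-fold AUC = 0.838
radiomics_tx    mean 10-fold AUC = 0.783
radiomics_prot  mean 10-fold AUC = 0.778
integrated_all  mean 10-fold AUC = 0.819
hold-out test AUC = 0.829; log-rank p = 2.65e-05; HR = 0.39 (0.25-0.61)
top 5 permutation importances: gene001, glcm_cluster_tendency,
  glcm_sum_of_squares_variance, glcm_cluster_prominence, intensity_variance
```

Reading: radiomics alone classifies survival well above chance (AUC
0.777); adding the genomic block with the planted mutation raises the
AUC; both planted features top the permutation-importance ranking (the
GLCM variance family is internally correlated, so its siblings rank
alongside); and the predicted short/long groups separate sharply on the
held-out set (median OS 112 vs 744 days in stage 5). The univariate
screen (stage 3) finds the planted radiomic feature most significant
after Holm correction (adjusted p = 6.3e-13, HR = 3.43, CI 2.47–4.77).
The negative control in stage 5 — the identical model on a cohort with
no planted effects — stays at chance (mean CV AUC 0.430).

Single-ROI extraction is one call:

```r
library(radsurv)
lesion <- generate_lesion(c(32, 32, 32), radius_mm = 8,
                          texture_scale_mm = 3, seed = 7)
feats <- extract_all(normalize_intensity(lesion$volume), lesion$mask)
feats["glcm_sum_of_squares_variance"]
```

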