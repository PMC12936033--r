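---
title: "Habitat radiomics for tumor grading: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics for tumor grading: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`habicat` implements a habitat-radiomics analysis for predicting the
pathological grade of lung tumors from CT: instead of summarizing the whole
tumor with one feature vector, the tumor (plus a thin peritumoral ring) is
partitioned into intensity/texture-coherent subregions — *habitats* — and
radiomic features of the habitats enter the classifiers alongside
whole-volume and clinical features. This vignette explains each stage's
model, the parameters that matter, the synthetic phantom used to validate
everything, and the design decisions that were genuinely open.

## Geometry: the whole volume of interest

The gross tumor volume (GTV) mask is expanded by a physical margin (default
3 mm) to capture the peritumoral zone; the expansion is clipped to the lung
mask so it never enters the chest wall. The union of GTV and ring is the
whole volume of interest (WVOI). Distances are Euclidean between voxel
centers in millimetres with an *inclusive* threshold, so a single-voxel GTV
at 1 mm spacing expands to the 123 integer lattice points with
$x^2+y^2+z^2 \le 9$ — a closed-form oracle the tests recompute by brute
force. Images and masks are resampled to 1 mm isotropic voxels beforehand;
nearest-neighbor interpolation is the default for both (trilinear is
available for the image via `interpolation = "linear"`, but the default
mirrors the mask dialect so that resampling never invents intensities).

## Voxel-wise entropy and habitat clustering

For every WVOI voxel the first-order entropy of its local neighborhood is

$$H = -\sum_{i=1}^{N_g} p(i)\,\log_2\!\big(p(i) + \varepsilon\big),$$

where the histogram has a fixed count of $N_g = 25$ equal-width bins
spanning the WVOI-wide intensity range (shared by all kernels of a subject,
so $p(i)$ is comparable across voxels), $\varepsilon \approx 2.2\times
10^{-16}$ guards empty bins, and the kernel is a $3\times3\times3$
neighborhood restricted to WVOI voxels. The kernel size is not dictated by
the method description we follow, so it is a configurable parameter
(`kernel_radius_voxels`, default 1 — the common voxel-wise radiomics
choice). Two readings of the histogram were possible — per-kernel or
WVOI-global; a global histogram would make the map constant, so the
per-kernel form is implemented. Entropies are bounded by
$[0, \log_2 25 \approx 4.64]$ bits and the map is invariant to affine
rescaling of the WVOI intensities, both tested properties.

Each voxel then contributes a super-voxel vector (raw intensity, entropy);
both channels are z-standardized across the WVOI before K-means because the
channels have incommensurate units (a zero-variance channel maps to zeros).
K-means runs with 10 random restarts from a fixed derived seed; clusters are
relabeled by descending mean raw intensity so habitat 1 is always the
brightest, with ties broken by cluster index. The number of clusters is
chosen cohort-wide: for each candidate $k \in \{2,3,4\}$ the per-subject
mean silhouette and Davies-Bouldin index are averaged over the cohort, and
the $k$ with the best mean silhouette wins (if the two metrics disagree the
disagreement is logged and silhouette decides). Silhouette and DB are
computed on a random subsample of at most 1000 voxels per subject because
both are $O(n^2)$; the subsample size only affects metric noise, not the
labeling. Singleton clusters get silhouette 0; coincident clusters get a
large DB sentinel so degenerate solutions are never preferred.

On phantoms the WVOI genuinely contains three intensity populations (lung
ring plus two tumor components), so cohort-wide selection may legitimately
return $k=3$ there; the two brightest habitats are then the tumor
subregions. This differs from real chest CT, where the peritumoral lung is
less cleanly separated — one of several respects in which passing phantom
tests does not certify behavior on patient data.

## The 851-feature schema

Each region (WVOI, Habitat 1, Habitat 2) yields 851 named features:

* 13 shape features computed on the voxelized mask (voxel-counting volume,
  exposed-face surface area, sphericity, maximum 3-D and per-plane 2-D
  diameters between voxel centers, PCA axis lengths, elongation, flatness);
* 19 first-order statistics on the raw intensities (population moments,
  Pearson kurtosis — a normal distribution scores 3 — percentiles with the
  linear-interpolation convention, energy, histogram entropy/uniformity on
  the 25-bin discretization);
* 75 texture features: GLCM (24), GLRLM (16), GLSZM (16), GLDM (14),
  NGTDM (5), all on intensities discretized to a fixed count of 25 bins over
  the region's min-max range. GLCM and GLRLM are computed per 3-D direction
  (13 unique directions) and feature values averaged; GLSZM zones are
  26-connected components of equal gray level; GLDM uses dependence
  threshold 0 and dependence size = dependent neighbors + 1;
* 744 wavelet features: a single-level *undecimated* 3-D Haar decomposition
  produces 8 sub-bands (LLL..HHH) on the original grid, and each sub-band
  contributes the first-order block minus TotalEnergy (18) plus the full
  texture block (75), i.e. 93 features per band.

The published composition (13 + 19 + 75 + 744 = 851) is internally tense:
19 first-order + 75 texture is 94 per band, but 744/8 = 93. The schema
resolves this by dropping TotalEnergy from the wavelet bands — it is the
voxel-volume-scaled duplicate of Energy and the least informative casualty —
and asserts the 851 total at construction. Undefined values on degenerate
regions (e.g. kurtosis of a constant region) take their analytic limit where
one exists and 0 otherwise, and the region is flagged; this keeps the table
dense for LASSO. Regions smaller than 10 voxels are extracted but flagged.
The wavelet filter choice (Haar, undecimated so the mask applies unchanged)
is the package's own; tests verify the filter-bank identities directly
rather than assuming any particular reference filter.

First-order and GLCM values are verified against independent brute-force
oracles written inside the test suite (direct moment formulas; naive
pair-enumeration co-occurrence counting), and the GLSZM large-area
low-gray-level emphasis against a fully hand-computed zone matrix.

## Batch harmonization

Features from the three simulated acquisition batches are harmonized with
reference-batch ComBat: each feature is standardized against the reference
batch (the largest by default), per-batch location/scale shifts are
estimated on that scale and shrunk by the parametric empirical-Bayes scheme
(normal prior on locations, inverse-gamma on scales, moment-matched
hyperparameters, fixed-point iteration to 1e-8), and non-reference rows are
adjusted while reference rows pass through bit-identically. No biological
covariates are adjusted. The implementation is in-package because the
pipeline needs a serializable fit/apply split; tests cross-check it against
the canonical Bioconductor implementation. Zero-variance features pass
through unharmonized with a warning. Harmonization is fitted once per
classification step on the concatenated (WVOI + H1 + H2) table *before* the
train/test split, mirroring the study design being reimplemented; this is a
documented leakage trade-off, and fitting per region or on training rows
only is available through the same functions.

## Two-step classification

Grading is decomposed into two binary steps: step 1 separates Grade 3 from
Grades 1–2; step 2, on Grade 1/2 subjects only, separates Grade 1
(positive) from Grade 2. Each step trains four logistic-regression
classifiers — whole-volume radiomics, habitat radiomics (H1 + H2 columns),
the 13 clinical features, and a combined model whose candidate pool is
exactly the union of the features the first three selected (refit without
further selection). The per-classifier pipeline, fitted on training rows
only, is:

1. outlier clipping to $[Q_1 - 3\,\mathrm{IQR},\; Q_3 + 3\,\mathrm{IQR}]$
   and z-scoring (parameters stored and reused on test rows);
2. SMOTE to exact class balance (synthetics interpolate between a minority
   point and one of its 5 nearest minority neighbors); by default SMOTE is
   applied *inside* each CV fold during lambda tuning, the leakage-safe
   reading of an unstated detail, with a whole-train mode available;
3. mRMR filter to 30 candidates (quotient scheme: F-statistic relevance
   over mean absolute correlation with already-selected features; ties by
   column order);
4. LASSO logistic regression with lambda chosen by 5-fold CV deviance;
5. a final logistic fit with a mild CV-tuned L2 penalty (unpenalized LR can
   separate after SMOTE on small cohorts), threshold fixed by Youden's J on
   the training ROC.

The selection order mRMR-then-LASSO (a fast filter before the embedded
selector) is a design choice where the source is silent; the 7:3 stratified
split, 5-fold CV, and SMOTE are as specified. A single master seed derives
every stage seed via a small integer hash, so the entire run is bit
reproducible and no stage's randomness can collide with another's.

## Evaluation

AUC uses the Mann-Whitney estimator (ties count 1/2; equal to trapezoidal
ROC integration). Variances, 95% CIs and paired comparisons use the DeLong
structural-components estimator, implemented in-package and cross-checked
against pROC; self-comparisons return p = 1, and single-member classes
return NA with a warning rather than a fabricated p. Sensitivity and
specificity on the test set reuse the training-derived threshold — any
test-side threshold choice would be leakage — and balanced accuracy is
exactly their mean. Feature attributions use exact linear SHAP in log-odds
space, $\phi_j(x) = \beta_j (z_j - \bar z_j)$, which is deterministic and
additive to the model's log-odds; sampling approximations would add noise
without changing the ranking semantics. Report tables round half-up to two
decimals.

## The phantom: what it emulates and what it does not

Each synthetic subject is an ellipsoidal tumor (per-axis radii uniform in
6–10 mm by default) inside a box-shaped lung at −700 HU-like units, with a
planted two-component structure: a dark core ("A", −80) forming an inner
ellipsoid scaled so its voxel fraction matches the subject's grade-dependent
mean (10% / 35% / 60% for Grades 1/2/3, subject SD 0.08), and a brighter
shell ("B", +40), each with Gaussian texture (SD 20). Batch effects are
injected at *feature* level — the level at which harmonization operates — as
an affine map per feature and batch whose ground truth (mean displacement in
SD units, variance scale) is recorded for recovery tests. The 13 clinical
features come from latent-threshold models: a grade-loaded latent Gaussian
(loading $1.6\rho$, clamped to ±0.95) thresholded into binary/ordinal
categories or mapped affinely for continuous ones, the simplest mechanism
that guarantees each configured correlation sign (density the strongest
positive at 0.42, tumor-lung interface negative, age/position near zero).

For the classifier-ordering experiment (habitat model outperforming the
whole-volume model) the generator has a dedicated `habitat_only_signal`
mode: the two component means are re-centered per subject so the tumor
mixture mean is constant across grades, and per-subject nuisance is added in
component separation (×0.6–1.6), texture scale (×0.7–1.5), noise skewness
(random gamma shape and orientation) and a global intensity offset (SD 40).
This emulates inter-patient appearance variability: per-subject clustering
adapts to it, pooled whole-tumor histogram statistics do not. The ordering
experiment uses overlapping grade fractions (0.20/0.32/0.50) because a
saturating effect size drives both classifiers to AUC 1.0, where an ordering
cannot be observed. These conditions were fixed as the experiment's design;
the acceptance suite then measures the ordering across 20 independent
replicates.

The phantom deliberately omits realistic lung anatomy, respiratory motion,
scanner physics, and spatially correlated noise. Passing its tests
demonstrates that every algorithmic stage recovers known ground truth under
its stated assumptions — not that the published patient-level AUCs would
reproduce, which requires the original cohorts.

## Problem sizes and numerical choices

Test and acceptance runs use scaled-down cohorts chosen as the package's
own validation sizes: 20 subjects per grade on 30³ grids for the end-to-end
study, 26³ grids and 15–20 subjects per grade for replicated experiments,
100 subjects per batch for harmonization recovery, and 1000 replicates for
type-I error and CI coverage. K-means uses 10 restarts and 100 iterations;
the EB fixed point iterates to 1e-8; LASSO uses glmnet's default lambda
path; cluster metrics subsample at 1000 voxels; the DB sentinel is 1e12.
Degenerate guards: constant WVOI gives an all-zero entropy map (not an
error); empty masks after resampling, unseen batch ids, and missing feature
columns are errors naming the offender; a GTV outside the lung warns and
keeps the GTV verbatim while clipping only the ring.

## Known limitations

* Shape features are voxel-based (no mesh), so surface-dependent values
  differ from mesh-based implementations by construction; the conventions
  are documented per feature and frozen by oracle tests.
* Harmonization-before-split reproduces the reimplemented design but leaks
  batch statistics across the split; use fit-on-train for deployment.
* Cohort-wide k selection assumes one cluster count fits all subjects.
* The linear SHAP module supports the logistic models this pipeline trains,
  not arbitrary classifiers.
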