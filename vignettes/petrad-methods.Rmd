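---
title: "Methods: PET/CT radiomics outcome modelling with petrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET/CT radiomics outcome modelling with petrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`petrad` implements a complete desk-scale pipeline for binary treatment-outcome
prediction (overall survival, OS, and disease-free survival, DFS) from
pre-treatment FDG PET/CT of head and neck squamous cell carcinoma:

1. a synthetic phantom cohort generator standing in for access-restricted
   patient data;
2. PET/CT preprocessing and the standard PET parameters SUV~peak~, MTV and TLG;
3. a curated radiomics feature set (first-order, shape, GLCM, GLSZM, GLRLM,
   3D LBP) computed within the primary gross tumor volume (GTVp);
4. RENT stability feature selection with its brute-force repeated-CV
   frequency protocol;
5. a model family M1–M7 (logistic regression, bagged forest, fully connected
   networks without/with interactions, and a small 3D squeeze-excitation CNN
   on 2/3/4 input channels);
6. nested five-fold cross-validation with ensemble averaging and
   class-balanced bootstrap metrics;
7. VarGrad gradient-variance saliency with quantitative stratification of
   heatmaps by SUV, HU and tumor/node/other location.

Both endpoints are coded so that class 1 is an event (death for OS; local,
regional or metastatic failure or death for DFS).

## The phantom generator: what it emulates and what it does not

The generator (`phantom_spec()`, `generate_cohort()`) produces, per patient, a
PET volume in SUV units, a CT volume in HU, binary GTVp/GTVn masks on a 1 mm
isotropic grid, a clinical covariate table, and binary endpoints. Its defaults
*are* the stated world of the emulated study population:

* **Endpoints.** Default event-rate targets are 0.49 (DFS) and 0.41 (OS); the
  logistic intercept is calibrated by root-finding so the cohort-average event
  probability hits the target given the planted effects.
* **Uptake.** Tumor amplitude is drawn uniformly on 5–17 SUV, centering
  SUV~peak~ near 11 with hot tumors in the 5–25 range on a background of
  1 SUV. Texture heterogeneity is a smoothed Gaussian field added inside the
  tumor; its amplitude (default 1.5 SUV) is the single heterogeneity knob and
  is what gives GLCM/GLSZM/GLRLM features signal to detect.
* **CT.** Soft tissue at 45 HU, +30 HU structure contrast inside tumor/nodes,
  10 HU white noise — values chosen to sit inside the narrow 70±100 HU
  window.
* **Geometry.** Tumors are deformed ellipsoids (semi-axes 8–15 mm; radial
  deformation field with per-patient amplitude drawn uniformly on 0–2x the
  configured mean), restricted to their largest 26-connected component. The
  semi-axis draw is capped so every tumor fits its grid.
* **Clinical covariates** are sampled independently with the study-population
  marginals (77% male, site mix dominated by oropharynx, 57.6% HPV-related,
  48.2% stage III–IV, etc.). HPV positivity is only assigned to oropharyngeal
  tumors, preserving the definitional coupling.

The phantom is deliberately abstract: no organ atlas, no scanner physics, no
partial-volume effects, no covariate correlations. A green test on phantom
data establishes that the *computational pipeline* behaves as specified
(protocol counts, oracle equivalence, recoverability of planted effects); it
does not establish clinical performance on real cohorts, which remain
access-restricted.

## Imaging conventions

* **CT windowing** clips to center 70 HU, width 200 HU, then maps affinely to
  [0, 1]; windowing feeds only the CNN input. Radiomics on CT are computed on
  raw HU, since the windowing step belongs to CNN preprocessing, and this is
  recorded in each feature's provenance.
* **PET scaling** divides by the SUV cut-off 25 after clipping; the cut-off
  can be re-derived as the 95th percentile (linear-interpolation quantile,
  type 7 — the convention had to be fixed and is documented here) of
  per-patient SUV~max~ over a training cohort.
* **SUV~peak~** maximizes the mean PET value over 1 cm³ spheres whose centers
  run over the voxel centers inside the GTVp (radius from (4/3)πr³ = 1000 mm³,
  r ≈ 6.2035 mm). Sphere membership is by voxel-center distance; spheres may
  extend beyond the GTVp, and voxels beyond the image grid are excluded from
  the mean. These choices make the quantity deterministic and checkable
  against an exhaustive brute-force oracle, which the test suite does on 100
  random phantoms at ≤ 1e−9 relative error.
* **MTV** counts GTVp voxels at or above 50% of SUV~peak~ (reported in cm³);
  **TLG** multiplies MTV by the mean SUV over the *whole* GTVp — the literal
  reading of the defining text, rather than the also-common mean over the MTV
  region.
* **VOI cropping** to the fixed 191 × 265 × 173 mm box is centered on the
  centroid of GTVp ∪ GTVn and clamped to the grid (the placement was
  unspecified; centroid-centering is reproducible and keeps the targets in
  frame), zero-padding where the box exceeds the volume.

## Radiomics numerical choices

* **Mesh sphericity.** Sphericity = π^(1/3)(6V)^(2/3)/A needs a surface mesh.
  Marching tetrahedra on the raw binary mask overestimates the area of a
  digital ball by several percent (staircase facets), so the mask is
  zero-padded and smoothed with a 3×3×3 mean filter before iso-surfacing at
  0.5. On a digital ball of radius 15 mm this yields sphericity ≈ 0.994 and a
  mesh volume within 0.1% of the analytic value. Degenerate regions that
  vanish under smoothing (single voxels) fall back to meshing the raw mask.
* **Elongation** is sqrt(λ₂/λ₁) of the physical-coordinate covariance
  eigenvalues (λ₁ largest; population convention), 1 by convention for a
  single voxel; the major axis length is 4√λ₁; the maximum 3D diameter is the
  largest pairwise distance between surface-voxel centers.
* **Discretization** defaults to a fixed bin count of 32 per modality;
  multiple binning settings may be requested and exact duplicate feature
  columns are removed afterwards (exact equality, not tolerance-based — the
  documented rule).
* **Texture conventions**: symmetric GLCMs at distance 1 over the 13 unique
  3D directions with per-direction feature averaging (not merged matrices);
  26-connected GLSZM zones; GLRLM runs over the same 13 directions. All are
  verified voxel-by-voxel against independent enumeration oracles on random
  grids.
* **3D LBP** thresholds `n_points` spherically sampled neighbors (octahedron
  vertices for the default 6; Fibonacci sphere otherwise; trilinear
  interpolation with replicate edge handling) at the center value. A neighbor
  exactly equal to the center counts as 1 — ties are common in discrete
  phantoms, so the rule matters and is fixed. Features are the normalized
  histogram bins named `LBP_000`, `LBP_001`, …; the original study's LBP
  feature indices are not defined in its main text, so this indexed-histogram
  naming is an explicit stand-in.
* **First-order list** is fixed and documented (mean, median, min, max,
  maximum-discretized, range, variance, skewness, kurtosis, histogram
  entropy, energy, 10th/90th percentiles, IQR, robust mean absolute
  deviation), with population moment conventions and non-excess kurtosis.

## RENT

A RENT run fits K elastic-net logistic models (glmnet) on K stratified
subsamples (fraction 0.8, without replacement — the source describes only
"unique subsets") and summarizes each feature by three criteria: c1, the
fraction of models with nonzero weight; c2, |Σ sign(w)|/K; c3, a one-sample
t-test of the K weights against zero (one-sided in the direction of the
observed mean). The thresholds are not stated in the source; the defaults
here are τ₁ = τ₂ = 0.9 and p < 0.05, all exposed in `rent_config()`.

The brute-force wrapper runs RENT on the training side of a repeated
stratified K-fold scheme (5 splits × 20 repeats = 100 runs per hyperparameter
combination), reports per-feature selection frequencies in percent, and picks
the hyperparameter combination with the best mean held-out performance. The
scoring metric is configurable with scaled MCC as default (chosen for
class-imbalance robustness; the source does not name its metric).
Standardization is fit on each training partition only and applied to its
held-out fold, preventing leakage (the source is silent; leaking would
inflate frequencies).

## Models

All models expose `predict_proba()` returning class-1 probabilities in
[0, 1]; hard labels are 1 iff probability ≥ 0.5, exactly.

* **M1** is glmnet logistic regression (ridge by default).
* **M2** is a from-scratch bagged CART/gini forest (no forest package exists
  in the target environment). Zero-gain splits are allowed while a node is
  impure, which is required for XOR-type targets.
* **M3/M4** are manual-backprop fully connected networks (ReLU hidden layers,
  sigmoid output, Adam, optional dropout, BCE or focal loss). M4 prepends an
  explicit pairwise-product interaction block to the input — an interpretable,
  testable stand-in for the unavailable original construction, and the tests
  confirm it beats M3 on a pure-interaction target at fixed width.
* **M5–M7** share one 3D CNN in the EfficientNet mold: stem convolution
  (stride 2), mobile-inverted-bottleneck blocks (pointwise expansion,
  depthwise 3³ convolution, squeeze-excitation, pointwise projection,
  residual when shapes match), global average pooling, dropout, sigmoid head.
  Channels are (PET, CT), + GTVp, + GTVn for M5/M6/M7. The architecture
  details of the original downscaled EfficientNet3D are unavailable, so this
  MBConv-3D design is an explicit stand-in with width/depth/dropout knobs
  exposed; the default "tiny" profile trains on one CPU for 32³ inputs in
  minutes. Forward and backward passes are hand-derived on compiled
  convolution kernels and verified against central finite differences. There
  is no batch normalization: at this scale He initialization plus Adam is
  sufficient and keeps the backward pass simple. The SE bottleneck bias is
  initialized slightly positive (0.1) so its gates are live at
  initialization.
* **Hyperparameter scoring** uses the weighted mean of validation AUC, scaled
  MCC, both per-class F1 scores and the training class-1 F1, with equal
  weights by default (the original weights are unavailable).

Seeded training is reproducible bit-for-bit under single-threaded BLAS; with
multi-threaded BLAS reductions the CNN/FCNN forward passes remain
deterministic but cross-machine bit identity is not guaranteed.

## Evaluation protocol

Folds are stratified on stage I–II vs III–IV, dealing shuffled stratum
members round-robin with a rotating offset so fold sizes differ by at most
one. Nested CV trains, for each of the 5 test folds, one model per
validation-fold rotation on the remaining 3 folds (4 models per test fold, 20
total — the "repeated five times" of the source protocol is read as the five
outer test folds each with four validation rotations); the per-patient
internal prediction is the ensemble average of its fold's 4 models, and
external cohorts are predicted by averaging all 20. Combined models average
class probabilities across model families.

Metrics: accuracy, rank-statistic AUC (ties at 1/2), MCC rescaled to [0, 1],
F1 on class 1 and on class 0 (class 0 as positive), precision, recall,
specificity. Degenerate denominators report 0 with a flag — deterministic and
auditable. Bootstrap metrics draw, per replicate, equal counts from each
class with replacement; the count is the minority class size (2 × min class
size per replicate), preserving the data scale without oversampling the
minority beyond its size. 1000 replicates by default; medians with 2.5/97.5
percentile intervals are reported.

## VarGrad

Saliency is the gradient of the class-1 output with respect to every input
voxel/channel; the default target is the sigmoid probability (the model is
defined as prediction = f(input)), switchable to the logit. VarGrad perturbs
the input with Gaussian noise (sd = 0.05 × per-channel dynamic range by
default; the source says only "adding noise"), recomputes saliency 20 times,
and takes the per-voxel variance, normalized by its global maximum (implied
by the bounded 0.25 display threshold). The variance uses a shifted two-pass
formula so an affine model's map is *identically* zero — the analytic
degenerate case used as a test. Multi-channel maps are reduced by
across-channel maximum for overlays; per-channel maps are kept for
stratification. Stratification bins follow the reported analysis: SUV edges
(0, 2, 10, ∞), HU edges relative to the 70 HU window center, and
tumor/node/other regions with tumor precedence on overlap; empty strata are
reported as absent (`NA`), never as importance 0.

## Design decisions that were genuinely open

* Sphere centers for SUV~peak~ restricted to voxel centers (continuous
  optimization would be non-deterministic across platforms and is not
  oracle-checkable).
* Exact-equality deduplication of radiomics columns (tolerance-based rules
  would make the kept set depend on column order in surprising ways).
* The percentile convention for the SUV cut-off, the balanced-bootstrap
  replicate size, the RENT thresholds and grid metric, the M4 interaction
  mechanism, the CNN architecture and the VarGrad noise model are all
  documented stand-ins for unavailable supplementary details, each exposed as
  configuration rather than hard-coded.

## Known limitations

* The phantom's independence assumptions (covariates, nodes, texture) mean
  selection frequencies on phantom data should not be read as clinical
  feature importance.
* The CNN is a deliberately small stand-in; no claim is made of parity with
  the original EfficientNet3D, and full-scale GPU training is out of scope.
* Radiomics cover the named feature subset, not the full 374-feature panel;
  wavelet/filtered classes and IBSI certification are out of scope.
* NIfTI I/O supports the subset the pipeline writes (3D, float32/uint8,
  little-endian), not the full standard.
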