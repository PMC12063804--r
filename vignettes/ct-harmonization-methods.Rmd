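---
title: "Harmonizing CT protocol variability: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing CT protocol variability: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctharmony)
```

## The problem

Radiomic features — large sets of handcrafted intensity and texture
statistics computed from regions of interest (ROIs) in medical images — are
sensitive to how a CT scan was reconstructed. The same object, reconstructed
with a different algorithm (filtered back projection vs iterative
reconstruction), a different convolution kernel, or a different slice
thickness/spacing, yields systematically shifted feature values. This
"batch effect" degrades both the test-retest reproducibility of features and
their power to discriminate tissue classes across protocols.

`ctharmony` implements and evaluates three remedies on a synthetic
multi-protocol liver-phantom study:

1. **feature-level harmonization**: reference-batch ComBat applied per ROI;
2. **image-level harmonization**: a paired WGAN-GP image-to-image
   harmonizer mapping each protocol arm onto a reference arm;
3. **their sequential combination**: images are GAN-harmonized first, then
   the extracted features are ComBat-harmonized (always in that order).

The package is organized around tidy feature tables (one row per
`(group, scan, roi)`, one column per feature), so the whole analysis chains
with the pipe. Volumes are plain 3D arrays with spacing and an integer ROI
mask (`labeled_volume`), read and written as NIfTI-1.

## The study design being emulated

The synthetic study mirrors an eight-arm reconstruction experiment on a
single anthropomorphic abdominal phantom: arms differ in algorithm
(FBP/IR), kernel class (a sharper "26f" and a smoother "30f" soft-tissue
kernel), slice thickness (1–3 mm) and spacing (0.75–2 mm); see
`ct_group_configs()`. Arm 7 (IR, I30f, 2 mm / 1 mm) is the reference:
iterative reconstruction is the common clinical choice and its geometry sits
near the middle of the design. Each arm carries 30 test-retest scans, and
four liver-region tissue classes are annotated: normal liver (1), benign
cyst (2), hemangioma (3), metastasis (4).

Two simulation layers exist, and they serve different purposes:

* `generate_phantom()` + `apply_acquisition()` build labeled HU volumes and
  push them through a protocol-dependent acquisition operator. The operator
  is deliberately minimal: kernel sharpness is a Gaussian point-spread
  function sigma (defaults: 0.6 mm for "26f", 1.0 mm for "30f"; kernel
  labels are qualitative, so a parametric numeric stand-in is required), slice thickness is a box average along z followed by
  resampling to the slice spacing and back, and the algorithm enters purely
  as a noise-amplitude multiplier (FBP × 1.5). ROI geometry is six
  ellipsoidal blobs (two normal-liver, two cyst, one hemangioma, one
  metastasis) placed at seeded random positions inside a liver-like
  super-ellipsoid. Texture is Gaussian noise smoothed at each tissue's
  correlation length and then standardized *exactly* to the tissue's
  mean/sd; smoothing correlates neighbouring voxels, which would otherwise
  make the empirical ROI mean drift beyond the naive `sd/sqrt(n)` band, so
  the calibration is exact rather than asymptotic. Tissue HU statistics
  (`tissue_specs()`) are textbook abdominal magnitudes inside the
  `[-45, 125]` HU window, not calibrated to any physical phantom, and are
  fully overridable.
* `simulate_feature_table()` draws feature tables directly from the ComBat
  generative model
  \(y_{ij} = \alpha + \beta X_{ij} + \gamma_i + \delta_i\,\varepsilon_{ij}\),
  with known per-batch effects attached as metadata. This is the ground
  truth used by the recovery and reproducibility tests. The study-default
  design (`default_sim_design()`) adds a unit-sd scan-level effect shared
  across arms: the 30 test-retest scans of a reconstruction study are the
  *same* raw acquisitions reconstructed eight ways, so scan-to-scan
  variation is common across arms. Without that shared component,
  scan-paired concordance against the reference arm would be near zero by
  construction and the reproducibility analysis would be meaningless.
  Remaining defaults, chosen once as plausible for standardized radiomic
  features: additive effects \(\gamma \sim N(0, 0.5)\), multiplicative
  effects \(\delta \sim U(0.8, 1.3)\) (reference arm fixed at 0 and 1),
  residual noise sd 0.15.

What the generator does **not** emulate: projection-domain physics
(sinograms, dose, beam hardening), printed-phantom material properties,
spatially varying noise texture, or anatomically realistic lesion shapes.
Tests passing on this generator therefore certify the statistical machinery
and its contracts, not performance on real phantom scans.

## Preprocessing

`standardize_volume()` resamples to isotropic 1 mm voxels (linear for
intensities, nearest-neighbour for masks), crops the tight bounding box of
voxels above −500 HU (a package default separating air and scanner bed from
the object), and resamples to a fixed grid, default 256 × 256 × 246. The
unusual axial value 246 is kept as the protocol default but is
configurable.
`clip_intensity()` clips to `[-45, 125]` HU; feature extraction runs on HU
values, and images are rescaled to `[0, 1]` over that window only at the
GAN boundary (`hu_to_unit()`), keeping feature definitions in physical
units.

## Feature extraction

`extract_features()` computes 93 non-shape features with IBSI-aligned
definitions: 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM
— the standard non-shape classes whose counts sum to 93. Implementation
notes that matter for comparability:

* fixed-bin-width discretization (default 25 HU) anchored at the ROI
  minimum; first-order statistics use raw HU;
* GLCM and GLRLM are computed per 3D direction (13 unique offsets at
  distance 1) and feature values averaged over directions, which makes the
  aggregated values invariant to 90° in-plane rotation of an isotropic ROI;
* GLSZM zones use 26-connectivity; the GLDM dependence count includes the
  center voxel (the NGLDM convention);
* percentiles use linear interpolation; entropies use log2 with
  \(0 \log 0 = 0\); degenerate moments (constant ROIs) return the defined
  limits (variance, entropy, contrast 0; uniformity and joint energy 1).

## Reference-batch ComBat

`combat_fit()` / `combat_transform()` implement location/scale batch
correction in reference-batch mode. Per feature: least-squares estimates
\(\hat\alpha\) (the reference batch's mean) and \(\hat\beta\) (covariate
coefficients, protected throughout); standardization by the reference
batch's residual variance; per-batch location \(\hat\gamma_i\) and scale
\(\hat\delta_i\) moments on the standardized scale; an empirical-Bayes step
shrinks them toward common priors (normal for location, inverse-gamma for
scale, both hyperparameterized by the method of moments across features).
The EB step is non-iterative — a single sweep computes \(\gamma^*\) given
the raw scales and \(\delta^*\) given \(\gamma^*\) — the simplest published
form of the estimator; on simulated tables it agrees with the established
iterative implementation in `sva::ComBat` to within a fraction of a percent
of the data scale, and `sva` is used as an independent cross-check in the
test suite, never as the implementation. The adjusted value is
\[
y^{ComBat} = \frac{y - \hat\alpha - \hat\beta X - \gamma^*}{\delta^*}
  + \hat\alpha + \hat\beta X,
\]
with the whole centered quantity divided by \(\delta^*\). Reference-batch rows are
returned untouched; constant features are flagged, warned about, and passed
through rather than dropped, keeping the table shape. `harmonize_per_roi()`
stratifies the whole procedure by ROI, since batch effects on radiomic
features are tissue-dependent.

This study has no biological covariates, so the design defaults to
intercept-only, but the covariate path is implemented and tested because
the model includes \(\beta X_{ij}\).

## The WGAN-GP image harmonizer

The generator is a shallow multi-receptive-field CNN: seven consecutive
stride-1 ReLU convolutions with kernel sizes 15, 13, 11, 9, 7, 5, 3 (all
seven outputs are retained), aggregated — concatenation by default,
summation available as a configuration flag — into a final tanh convolution whose output is added to the input
(the minimal residual blend) and clipped to
`[0, 1]` (a "ramp" activation on window-scaled intensities). The critic has four spectrally-normalized stride-2
convolutions with 32, 64, 128, 256 filters (kernel 5), LeakyReLU, dropout,
and a dense head producing one unbounded score.

Training alternates 5 critic updates per generator update (the WGAN-GP
convention) under RMSprop with initial learning rate
2·10⁻⁴ for both networks, exponential per-step decay (rate exposed in
`train_config()`), batch size 1, a 75/25 train/test split of the slice
pairs, and paired augmentation (rotations up to ±15°, flips, intensity
jitter ±0.05; the transform magnitudes are package defaults). The critic objective is the Wasserstein loss plus a
gradient penalty of weight 10 on uniformly interpolated samples. The
generator objective is
\[
L_{total} = \alpha L_{adv} + \beta L_{perc} + \gamma L_{L1}
  + \delta L_{nmse} + \epsilon L_{PSNR},
\quad (\alpha,\beta,\gamma,\delta,\epsilon) = (1, 1000, 100, 100, 100),
\]
with the PSNR term entering as a decreasing transform (negative PSNR,
normalized) so that minimizing the total loss increases PSNR. Both an L1 and an NMSE term are
implemented because the composite lists both.

All network arithmetic — convolution via im2col, backpropagation, RMSprop,
spectral normalization by warm-started power iteration, and the
second-order pass that differentiates the gradient-penalty term with
respect to the critic weights (activation patterns held fixed, exact almost
everywhere for piecewise-linear critics) — is implemented natively in R
with C++ kernels for the im2col/col2im gather–scatter. Exactness of every
gradient path is checked against finite differences in the test suite's
development history; the released suite asserts the analytic
gradient-penalty values, spectral-norm bounds, loss decomposition, and
training-improvement contracts.

The perceptual loss is backbone-agnostic and pluggable. The default
backbone is a fixed-seed random-convolution feature extractor (two conv
layers), which is self-contained and deterministic; random convolutional
features are a recognized basis for perceptual distances, and the loss
contract — zero at identity, differentiable, weighting per the composite —
does not depend on the backbone's provenance. A pretrained deep backbone
can be substituted where its weights are available.

## Evaluation

* **Reproducibility** (`reproducibility_report()`): Lin's concordance
  correlation coefficient, computed with population moments, between the
  30 scan-paired feature values of each arm and the reference arm, per
  (feature, ROI, arm). Scans are paired by index — the only pairing the
  test-retest design supports. Comparisons with a constant side (variance
  < 1e-12) are excluded (a CCC against a constant vector is undefined). Reported: average
  CCC and the fraction of comparisons with CCC ≥ 0.95.
* **Stability** (`stability_report()`): per (feature, ROI, arm),
  Shapiro–Wilk at 0.05 on the paired differences decides between the paired
  t test and the Wilcoxon signed-rank test (exact zeros dropped, the
  standard convention; an all-zero vector short-circuits to adjusted p = 1
  with a note); Bonferroni adjustment across the arm comparisons; a feature
  is stable for an ROI when every adjusted p exceeds 0.05.
* **Power** (`paired_power()`): two-sided paired-t power from the
  noncentral t distribution (noncentrality \(d\sqrt n\), df \(n-1\)).
* **Discriminative power** (`discrimination_report()`): correlation filter
  at |r| > 0.95 keeping the first feature of each offending pair by column
  order (deterministic tie-break), z-scoring, an RBF-kernel SVM tuned by
  grid search (C ∈ {0.1, 1, 10, 100}, γ ∈ {1/p, 0.01, 0.001}) under
  stratified 3-fold cross-validation, and per-class one-vs-rest AUC from
  held-out decision margins of explicit one-vs-rest binary SVMs, averaged
  over folds. Margins are used rather than Platt-scaled probabilities
  because probability calibration in libsvm consumes an unseeded internal
  RNG (breaking reproducibility) and mixes calibrations across folds;
  fold-wise margin AUCs are deterministic and rank-faithful. The grid is
  selected on the cross-validated macro AUC — the quantity the report
  exists to measure.
* **Image quality** (`image_quality()`): NMSE \(\|g-t\|^2/\|t\|^2\), PSNR
  \(10\log_{10}(R^2/MSE)\) capped at a configurable value for perfect
  reconstructions, and Gaussian-windowed SSIM (11 × 11, σ = 1.5,
  K₁ = 0.01, K₂ = 0.03) on the valid interior.
* `plot_feature_embedding()` is a qualitative 2D principal-component view
  of the standardized feature space; no numeric result depends on it.

## Orchestration

`run_subexperiment()` executes the three designs end to end on a synthetic
or supplied study and returns a bundle with the baseline and harmonized
feature tables, all four report types, a `method_summary()`, and a manifest
(seeds, configs, stage order, package version) sufficient to regenerate
every output bit-identically — all randomness descends from one master
seed through labelled child seeds. In the combined design the stage order
is always GAN first, then ComBat. `compare_methods()` assembles the
headline tables for the four designs (none / ComBat / GAN / GAN+ComBat)
and the relative percent change of each method against the non-harmonized
baseline, `100 (method − baseline)/baseline`, recorded in the output.

## Numerical choices and problem sizes

Tolerances: constant-feature detection at variance 1e-12; reference-batch
pass-through exact by construction and asserted at 1e-6; scale estimates
floored at 1e-12 to keep \(\delta^* > 0\). Macro AUC rows agree with the
arithmetic mean of per-ROI entries to 5e-3, the rounding precision of
two-decimal reporting.

The test suite exercises the imaging chain at reduced scale — phantoms of
24³–48³ voxels, 2–4 scans per arm, GAN smoke runs of a few hundred steps on
32 × 32 slices with the default generator width of 8 filters per texture
layer — sizes chosen so the full statistical pipeline, not a cartoon of it,
runs in an ordinary check. The feature-table analyses run at the full
design (8 arms × 30 scans × 4 ROIs × 93 features).

## Known limitations

* The acquisition operator reproduces the *premise* that arms differ
  texturally, not CT reconstruction physics; kernel sigmas and the FBP
  noise factor are stand-ins exposed in configuration.
* Tissue HU statistics are plausible defaults, not phantom calibrations.
* The non-iterative EB step differs from iterative refinement by amounts
  far below the batch effects it removes, but is not bit-identical to
  implementations that iterate.
* Training the harmonizer in R is practical at study scale but slow for
  large images; the architecture is faithful, not performance-tuned.
* SSIM uses zero-order boundary handling on the valid interior; values on
  images smaller than the window fall back to a reduced window.
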