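# ctharmony

Radiomic features extracted from CT images shift systematically with the
scanner's reconstruction settings — algorithm (filtered back projection vs
iterative reconstruction), convolution kernel, slice thickness and spacing.
`ctharmony` is an R package for removing this protocol-induced variability
and for quantifying what each remedy buys you. It is aimed at radiomics
researchers who need their feature tables comparable across acquisition
protocols, and at methodologists studying harmonization itself.

The package implements, end to end:

* **Reference-batch ComBat** at the feature level, applied per ROI: for
  feature values following

  y<sub>ij</sub> = α + β·X<sub>ij</sub> + γ<sub>i</sub> + δ<sub>i</sub>·ε<sub>ij</sub>

  (batch i, sample j, protected covariates X), empirical-Bayes estimates
  γ\*, δ\* of the additive and multiplicative batch effects are shrunk
  across features by the method of moments and removed:

  y<sup>ComBat</sup> = (y − α̂ − β̂·X − γ\*)/δ\* + α̂ + β̂·X,

  with the reference batch's data returned untouched.
* A **paired WGAN-GP image harmonizer**: a shallow multi-receptive-field
  CNN generator (seven ReLU convolutions, kernels 15…3, fused by a tanh
  convolution, residual blend, ramp output) trained against a
  spectrally-normalized convolutional critic under the Wasserstein loss
  with gradient penalty (weight 10), with the composite generator loss
  L = 1·L<sub>adv</sub> + 1000·L<sub>perc</sub> + 100·L<sub>L1</sub> +
  100·L<sub>nmse</sub> + 100·L<sub>PSNR</sub>. All network arithmetic is
  native R + C++ (no deep-learning runtime required).
* Their **sequential combination** (GAN first, then ComBat).
* A **synthetic multi-protocol phantom study** (8 reconstruction arms,
  test-retest scans, 4 liver-tissue ROIs) so every stage is runnable and
  testable without any external dataset.
* The full **evaluation suite**: test-retest reproducibility via Lin's
  concordance correlation coefficient (CCC), paired stability tests
  (Shapiro–Wilk–gated paired t / Wilcoxon with Bonferroni correction),
  paired-t power from the noncentral t distribution, SVM tissue
  classification AUC, and image quality (NMSE, PSNR, SSIM).
* An extractor for the **93 non-shape radiomic features** (18 first-order,
  24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) with IBSI-aligned
  definitions.

Feature tables are tibbles keyed by `(group, scan, roi)`; everything
composes with the pipe, fitted models have `tidy()`/`glance()` methods, and
reports have plot helpers.

## Worked example

Simulate a feature table under the study-default design (8 protocol groups,
30 test-retest scans, 4 ROIs, 93 features, known batch effects), harmonize
it to reference group 7, and measure what changed:

```r
library(ctharmony)

tbl  <- simulate_feature_table(default_sim_design())
harm <- harmonize_per_roi(tbl, reference_batch = 7)

reproducibility_report(tbl, harm, reference_group = 7)
#> <repro_report> CCC vs group 7 (threshold 0.95 )
#> # A tibble: 2 × 5
#>   set        average_ccc frac_reproducible n_comparisons n_excluded
#>   <chr>            <dbl>             <dbl>         <int>      <int>
#> 1 harmonized       0.973             0.965          2604          0
#> 2 original         0.873             0.337          2604          0
```

Before harmonization only ~34% of (feature, ROI, group) comparisons reach
the CCC ≥ 0.95 reproducibility bar; removing the batch effects lifts that
to ~97% with an average concordance of 0.97 — while group 7 itself is
bit-identical to its input. The achieved power of the per-feature paired
stability tests at the study's size:

```r
paired_power(effect_size = 0.5, alpha = 0.05, n_pairs = 30)
#> [1] 0.7539647
```

i.e. 30 test-retest pairs give 75.4% power against a medium (d = 0.5)
paired shift at α = 0.05.

The imaging pathway runs the same way from volumes:

```r
cfg <- pipeline_config(groups = c(3, 7), scans_per_group = 4,
                       shape = c(24, 24, 16),
                       gan = train_config(steps = 50))
rep <- run_subexperiment("combined", cfg)   # GAN, then ComBat, then evaluate
rep$stages
#> [1] "gan"    "combat"
```

and `compare_methods()` assembles the headline tables (average CCC, %
reproducible, per-ROI stability, per-ROI and macro AUC) for the four
designs — none / ComBat / GAN / GAN+ComBat — plus each method's relative
percent change against the non-harmonized baseline.

A thin command-line dispatcher over the same functions ships in
`inst/cli/ctharmony` (`simulate`, `extract`, `combat`, `evaluate`, `run`).

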