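# codenoise

Pattern uncertainty and controls-based denoising for image-derived
read-out patterns.

## What this is for

Group-difference *read-out patterns* are a standard clinical image-analysis
tool: compute the difference of mean images between patients and healthy
controls (e.g. voxel-based-morphometry gray-matter maps), then score each
subject by the pattern expression score (PES), the normalized projection
`PES = p·b / ‖b‖²`. Such scores suffer from two problems that this package
treats jointly:

* **The pattern is noisy.** With `N_P` patients and `N_H` controls, the
  expected squared Euclidean distance between the read-out pattern `b` and
  the true pattern behaves like a scalar squared standard error,

  ```
  SE²(b) = (1/N_P) Σ_j Var_P(j) + (1/N_H) Σ_j Var_H(j),
  ```

  summed over masked voxels. Its normalized form, the noise component
  estimator `NCe = SE²/‖b‖²`, is the fraction of the pattern's squared
  length that is sampling noise — worth reporting with any PES analysis.

* **The scores are diluted by nonpathological variance (NPV)** — age, sex,
  scanner, protocol. Controls-based denoising (CODE) learns NPV directions
  by PCA from an independent multi-center control sample (via the
  subject-space Gram matrix, so voxel count is never limiting) and removes
  them, fully or weighted: `b_w = b − w Σ_k (b·c_k) c_k`.

The central quantity is the **net benefit estimator**
`NBe = (1 − SRe)/(1 − NRe)`, built from the estimated signal reduction
(SRe) and noise reduction (NRe) of denoising, with SE²-based uncertainty
correction throughout. NBe predicts — from training data alone — the
factor by which the PES signal-to-noise ratio changes under denoising, so
harmful denoising (e.g. a disease pattern nearly collinear with an aging
pattern) is flagged *before* it damages a classifier, and the denoising
weight `w` can be optimized (`optimize_weight()`, with `w = 0` meaning
"don't denoise" always available).

Evaluation utilities include leave-one-pair-out scoring, ROC/AUC with
Youden operating points, one-sided DeLong AUC comparison, and the
after/before t-ratio that is NBe's empirical counterpart. A simulator of
the underlying linear pathology model
(`image = PSS·μ + NPV loadings + noise`) generates all test fixtures and
the scaled-down validation experiments.

## Worked example

Simulate a cohort with strong nonpathological variance, estimate the
pattern and its uncertainty, optimize denoising, and evaluate
leave-one-pair-out:

```r
library(codenoise)

scn  <- scenario_suite(seed = 1)$scz_like        # strong-NPV regime
inst <- scenario_instance(scn, seed = 2)         # cohort + NPV basis

inst$pattern
#> readout_pattern: 2000 voxels (n = 30 patients vs 30 controls)
#>   ||b||^2 = 1.32272   SE2 = 0.313841   NCe = 23.7%

opt <- optimize_weight(inst$pattern, inst$basis,
                       inst$patients, inst$controls)
opt
#> denoise_result (weighted CODE)
#>   w = 1.0000  (v = 1.0000)
#>   NRe = 92.7%   SRe = 17.6%   NBe = 11.2
#>   NCe of denoised pattern = 5.6%

run_lopo(inst$patients, inst$controls, inst$basis, list(seed = 3))
#> eval_report (leave-one-pair-out)
#>   folds: 30 (skipped 0)   mean w = 1.0000
#>   t before / after = 10.12 / 17.27  (t-ratio 1.71)
#>   AUC before / after = 0.964 / 1.000  (one-sided DeLong p = 0.0406)
#>   denoised Youden point: sens 1.00, spec 1.00
```

Reading this: 23.7% of the raw pattern's squared length is sampling
noise. Denoising removes 92.7% of the residual spread along the pattern
at the cost of 17.6% of its (uncertainty-corrected) signal, so the net
benefit estimator predicts a large improvement (NBe = 11.2) — and the
held-out evaluation confirms it (t-ratio 1.71, AUC 0.964 → 1.000). In the
collinear `pd_like` scenario the same pipeline instead returns `w* = 0`
and NBe < 1 at `w = 1`: denoising would remove the signal itself, and the
optimizer refuses.

NIfTI cohorts (one volume per subject + binary mask + CSV manifest) are
ingested with `load_cohort()`; patterns and NPV bases serialize to NIfTI
with plain-text sidecars. A thin command-line wrapper with `simulate`,
`pattern`, `pca`, `denoise` and `evaluate` subcommands lives at
`inst/cli/codenoise.R`.

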