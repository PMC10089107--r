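---
title: "Pattern uncertainty and controls-based denoising"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern uncertainty and controls-based denoising}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codenoise)
```

## The problem

A widely used way to quantify disease-related change in image-derived
maps (for example voxel-based morphometry gray-matter maps) is the
pattern expression score: project a subject's image onto a
*read-out pattern* — the difference of group mean images between
patients and controls — and use the normalized dot product as a
per-subject severity score. Two things limit this score in practice:

1. the read-out pattern is estimated from a finite sample and therefore
   noisy, and
2. the score is diluted by *nonpathological variance* (NPV): age, sex,
   scanner and protocol effects that dominate healthy anatomy.

`codenoise` implements a joint treatment of both: an analytic estimate
of the read-out pattern's sampling uncertainty, and controls-based
denoising (CODE) — removal of NPV directions learned from an
independent, only loosely matched multi-center control sample — with a
*predicted* net benefit that tells you, before touching the test data,
whether denoising will help or hurt.

## Model and estimators

The linear pathology model writes the image of subject $i$ as

$$ p_i = \mathrm{PSS}_i\,\mu + r_i, $$

with $\mu$ the true (unknown) pathology pattern, $\mathrm{PSS}_i$ the
subject's pathology-specific score, and $r_i$ a residual containing
physiological variance and acquisition noise. The read-out pattern is
$b = \bar p_P - \bar p_H$ over $N_P$ patients and $N_H$ controls, and
the pattern expression score of an image $p$ is
$\mathrm{PES} = p \cdot b / \lVert b\rVert^2$.

Because the Euclidean distance between random patterns decomposes over
voxels, the expected squared distance between $b$ and its population
mean behaves like a scalar squared standard error:

$$ \mathrm{SE}^2_b \;=\; \frac{1}{N_P}\sum_j \mathrm{Var}_P(j)
   \;+\; \frac{1}{N_H}\sum_j \mathrm{Var}_H(j), $$

computed from unbiased ($N-1$ divisor) per-voxel group variances. Its
scale-free companion is the noise component estimator
$\mathrm{NCe} = \mathrm{SE}^2_b / \lVert b\rVert^2$: the fraction of the
pattern's squared length attributable to sampling noise. `readout_pattern()`
returns both; `NCe \ge 1` marks a pattern statistically
indistinguishable from noise (returned, flagged, never silently
clamped). The per-subject error of reading out $\mathrm{PSS}$ with PES
has standard deviation estimated by `estimation_error_sd()`:
$\sigma(R\,b^\top) / \big((1-\mathrm{NCe})\lVert b\rVert^2\big)$, where the
residual matrix $R$ holds the controls used for pattern calculation,
centered on their own mean. The $(1-\mathrm{NCe})$ factor corrects for
the fact that $\lVert b\rVert^2$ is noise-inflated: without it the error
of noisy patterns is systematically underestimated.

## Controls-based denoising and its weighted form

`fast_pca()` learns NPV directions $c_k$ (unit norm, mutually
orthogonal) from an independent control sample via the subject-space
Gram matrix — equivalent to voxel-space PCA but tractable when voxels
far outnumber subjects. Standard CODE removes the projections
completely; weighted CODE removes a fraction $w$:

$$ b_w = b - w \sum_k (b \cdot c_k)\, c_k , $$

and identically for images (`denoise_images()`); removing from the
pattern or from the images commutes, which is the scoring shortcut the
package exploits.

For the bookkeeping of *signal* under partial removal the package uses
the companion weight $v = 1 - \sqrt{1 - w}$. Splitting
$b = b_\perp + b_C$ into out-of-span and in-span parts,

$$ b \cdot b_w = \lVert b_\perp\rVert^2 + (1-w)\lVert b_C\rVert^2
   = \lVert b_v\rVert^2 , $$

because $(1-v)^2 = 1-w$. This choice is not cosmetic: the noise
self-projection inside $b \cdot b_w$ also keeps a $(1-w)$ share of its
in-span energy, while the squared standard error of $v$-denoised data
keeps $(1-v)^2$ of it. With $(1-v)^2 = 1-w$ the two cancel exactly, so
$(1-\mathrm{NCe}^d_v)\lVert b_v\rVert^2$ is an unbiased estimate of the
true signal coefficient $\mu \cdot b_w$ in $w$-denoised scores. All of
this is checked to $10^{-10}$ by the identity tests.

Denoising effects are summarized by three estimators (fractions
internally, conventionally reported in percent):

* `nre()` — noise reduction: $1 - \sigma(R b_w^\top)/\sigma(R b^\top)$;
* `sre()` — signal reduction:
  $1 - \dfrac{(1-\mathrm{NCe}^d_v)\lVert b_v\rVert^2}
             {(1-\mathrm{NCe})\lVert b\rVert^2}$, with
  $\mathrm{NCe}^d_v$ recomputed from $v$-denoised subject data
  (`nce_denoised()`), which makes the denoised error formula
  structurally identical to the raw one;
* `nbe()` — net benefit: $(1-\mathrm{SRe})/(1-\mathrm{NRe})$, equal to
  the ratio of estimation-error sds before and after denoising.
  $\mathrm{NBe} > 1$ predicts improvement of the score's
  signal-to-noise ratio, $\mathrm{NBe} < 1$ predicts harm.

`optimize_weight()` minimizes the predicted error
$\sigma(R b_w^\top)/\big((1-\mathrm{NCe}^d_v)\lVert b_v\rVert^2\big)$ over
$w \in [0,1]$ subject to $\mathrm{NCe}^d_v < 1$. The problem is
one-dimensional, so a deterministic 21-point grid plus golden-section
refinement of the best bracket is used; ties break toward smaller $w$
and infeasible weights score $+\infty$. Since $w = 0$ is always a
candidate, optimized denoising is never *predicted* to be worse than
doing nothing — the worst case is a no-op.

## Evaluation

`run_lopo()` scores subjects leave-one-pair-out: one randomly matched
patient-control pair (seeded, `lopo_pairs()`) is held out, the pattern
is rebuilt and the weight re-optimized on the rest, and the held-out
pair is scored raw and denoised with matching normalizations. Reports
aggregate the equal-variance two-sample $t$ (its after/before ratio is
the empirical counterpart of NBe), the ROC area by the midrank formula
(ties at half weight — identical to Mann-Whitney pair counting), the
Youden operating point (ties broken toward specificity), and a
one-sided DeLong test of the AUC difference in the Sun-Xu midrank
formulation, cross-checked in the test suite against `pROC` and a
jackknife variance oracle. The NPV basis always comes from a separate
sample and is reused across folds.

## What the simulator emulates

`make_truth()` / `sample_cohort()` instantiate the linear model
literally: Gaussian PSS in patients (controls have PSS = 0 exactly),
Gaussian loadings on a random orthonormal NPV set, iid Gaussian voxel
noise. The first NPV direction can be rotated toward $\mu$ (the
`overlap` parameter) and NPV loadings can be age-coupled, which is what
makes the covariate-removal rescue testable. Gaussianity is a modeling
choice: the variance-based SE² formula needs second moments only, and
no distributional claims from real data are available to prefer
anything else. The simulator does **not** emulate spatial smoothness,
site/batch structure beyond NPV loadings, non-linear disease
progression, or correlation between PSS and NPV loadings (geometric
overlap is injected, statistical dependence is not). Passing tests
therefore demonstrate internal consistency of the estimators and the
qualitative regimes — not performance on real MRI.

Default study conditions: 2000 voxels, 10 NPV directions, cohorts of
2 × 30, NPV loading sds $0.6/\sqrt{k}$, voxel noise sd 0.02, patient
PSS ~ N(1, 0.25). These keep a Gram PCA stable in seconds-scale tests
while leaving the noise component estimator in a realistic 10–30%
range.

`scenario_suite()` freezes four regimes. Their parameters were chosen
from the model's expectation algebra (not fitted to any test):

* **ad_like** — defaults; NPV orthogonal to $\mu$, NCe ≈ 0.13. All
  denoising weight should be used and NBe ≫ 1.
* **scz_like** — NPV sds doubled: strongest benefit.
* **mdd_like** — weak effect (PSS mean 0.25, n = 2×40), NCe ≈ 0.6:
  discriminative almost only after denoising. The effect size keeps the
  sampling spread of $\lVert b\rVert^2$ (driven by the ~10 NPV degrees
  of freedom) clear of the NCe ≥ 1 degeneracy.
* **pd_like** — weak effect whose pattern has cosine 0.95 with a
  *purely age-driven* NPV direction (loading slope 0.0323 per year over
  ages 45–75), unstructured noise sd 0.07, PCA sample of 1000, top 10
  components retained. Two margins matter and both follow from the
  expectation algebra: the removable share of residual variance along
  $b$ must stay clearly below the removed share of signal (so that
  denoising is harmful for *every* $w > 0$, making $w^\ast = 0$ a
  stable optimum rather than a knife-edge), and the age-driven
  eigenvalue must sit far above the Marchenko-Pastur bulk edge of the
  PCA sample so the collinear direction is estimated accurately — which
  is also why this scenario uses the large PCA sample. Regressing age
  out of the PCA sample (`covariate_pattern()` / `remove_covariate()`)
  removes that direction from the basis entirely, after which full
  denoising is harmless again.

## Numerical choices and degenerate inputs

* Per-voxel variances use the unbiased $N-1$ divisor, matching the
  standard-error analogy; groups of fewer than 2 subjects are rejected.
* PCA mean-centers by default and stores the center; components with
  eigenvalue below $10^{-10}$ of the largest are dropped; component
  signs are fixed by making the largest-magnitude loading positive.
* All NPV components are retained by default — truncation is always an
  explicit caller choice (`truncate_basis()`), because the useful
  number of components is an experimental variable, not a constant.
* An empty basis makes denoising the identity (NBe = 1).
* Degenerate LOPO folds (zero-norm or noise-dominated patterns) are
  skipped with a warning; a run with more than 20% skipped folds is
  rejected.
* DeLong with zero variance returns p = 0.5 when the AUCs are equal and
  flags the contrast as degenerate otherwise.
* Voxel columns follow the mask's TRUE voxels in R's native array order
  (first index fastest, the NIfTI on-disk order), so patterns written
  to NIfTI re-ingest bit-exactly.

## Problem sizes used by the validation experiments

The packaged experiments are scaled to desk hardware: 2000 Monte-Carlo
cohorts for the SE² validation; 50 random instances for each exact
identity; PCA agreement on 5×8 through 20×50 toys; 20 repetitions of
the weight sweep with independent test cohorts of 2 × 300; 10
repetitions per PCA sample size in {20, 40, 100}. `scripts/acceptance.R`
re-runs all of them from scratch under a caller-supplied seed.

## Known limitations

The pattern expression score is linear, and so is everything built on
it here; non-linear disease progression at the voxel level is outside
the model. The net benefit estimator predicts the change in the
*score's* signal-to-noise ratio; the observed $t$-ratio additionally
contains between-patient severity variance, so agreement is expected in
sign and in the location of maxima, not in magnitude. Non-linear NPV
decompositions are out of scope.
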