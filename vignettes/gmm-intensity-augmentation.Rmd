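---
title: "Contrast augmentation via Gaussian-mixture intensity remapping"
author: "gmmaug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast augmentation via Gaussian-mixture intensity remapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmmaug)
```

## The model

`gmmaug` treats the masked voxel intensities of a skull-stripped
T1-weighted brain volume as draws from a K-component univariate Gaussian
mixture, p(v) = Σₖ πₖ N(v | μₖ, σₖ²), with K = 3 components that align
with the three dominant histogram modes: CSF (darkest), GM, WM
(brightest). The model is deliberately *aspatial* — it sees the histogram,
not the anatomy — which is exactly why it can alter contrast without
touching structure.

Augmentation perturbs the fitted component parameters within calibrated
uniform ranges and rebuilds the image so that every voxel keeps its
signed, variance-scaled distance d_vk = (v − μₖ)/σₖ to each original
component: vₖ′ = μₖ′ + d_vk·σₖ′, blended across components by the voxel's
*original* class posteriors. Two properties follow directly from this
algebra and anchor the test suite:

* **No-op identity.** With μ′ = μ, σ′ = σ the blend telescopes to
  Σₖ p(k|v)(μₖ + d_vk σₖ) = Σₖ p(k|v)·v = v: zero perturbation returns
  the input bit-for-bit (up to floating-point addition order).
* **Pure-voxel distance preservation.** A voxel with posterior ≈ 1 for
  component k maps to μₖ′ + d_vk σₖ′ exactly, so it represents the same
  tissue at the same within-class position afterwards. Only boundary
  voxels (mixed posteriors) are blended.

Both are verified to 1e-9 / 1e-6 in `tests/testthat/test-acceptance.R`,
together with an independent scalar per-voxel oracle of the whole
posterior-plus-remap computation (agreement ≤ 1e-10).

### Assumptions

The mixture reading of the histogram presumes (i) skull-stripped input —
background is exactly 0 and excluded via the mask; (ii) bias-field
corrected input — a multiplicative intensity gradient smears the class
modes together and the components stop corresponding to tissues (the
package's bias-field sensitivity check quantifies this on phantoms);
(iii) no dominant fourth intensity population (large lesion loads overlap
the GM mode and are not modeled separately).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `K` | 3 | components | CSF/GM/WM histogram modes of non-contrast T1w |
| `low_pct`, `high_pct` | 1, 99 | percentiles | robust clipping before rescaling to [0, 1] |
| `s_mu` | (0.03, 0.06, 0.08) | normalized intensity | published multi-centre SDs of fitted means (CSF, GM, WM) |
| `s_var` | (0.001, 0.001, 0.003) | squared normalized intensity | published multi-centre SDs of fitted variances |
| `tol` | 1e-6 | relative mean log-likelihood | see *Numerical choices* |
| `max_iter` | 500 | iterations | cheap per iteration; generous ceiling |
| `var_floor` | 1e-6 | variance | prevents component collapse and keeps σ′² > 0 |
| `clip` | `FALSE` | — | the remap can exit [0, 1]; clipping would silently break distance preservation, so it is opt-in |

Offsets are drawn from *uniform* intervals rather than a normal law: the
intent is to expose a training pipeline to extreme but structurally valid
contrast combinations, so the tails are not down-weighted. Perturbed
components keep their identity (index) even when means reorder or overlap
— such inversions are intentional, extreme augmentations; the
reconstruction never re-sorts them.

## Calibration

`estimate_ranges()` reproduces the range-calibration procedure: normalize
every image (clip 1/99, rescale to [0, 1]), fit the mixture, and report
the per-component *sample* standard deviation (n − 1; the definitional
oracle test pins this convention) of the fitted means and variances
across images, matching components by ascending mean. Estimates are
order-invariant and failed fits are skipped with a warning.

One consequence of the normalization deserves emphasis. Rescaling anchors
every image at its own 1st/99th percentiles, and in a three-mode
histogram those anchors are tied almost one-to-one to the darkest and
brightest class means. Between-image variation in the *extreme* class
means is therefore largely absorbed into the anchors, while variation in
the middle class is amplified by the fluctuating range denominator: the
estimated half-widths describe variability of the normalized contrast,
not of raw tissue intensities. On synthetic collections with iid
per-class mean dispersion of SD 0.05, the full pipeline returns roughly
(0.03, 0.1, 0.03) rather than 0.05 everywhere — not an estimator defect
but a property of anchored normalization (with `preprocess = FALSE` the
same estimator recovers the injected 0.05 per component to well within
sampling error, as both the unit tests and `scripts/acceptance.R`
compute). The packaged defaults are used on the same normalized scale on
which they were derived, so this subtlety does not affect augmentation
itself.

## The phantom generator

`generate_phantom()` builds the study volumes: nested ellipsoids (WM
core, GM shell, CSF shell, plus a central ventricle labeled CSF) with
per-class Gaussian intensities at means (0.2, 0.5, 0.8) and SD 0.02 by
default — well-separated modes of roughly equal volume fraction, the
regime in which the CSF/GM/WM reading of the mixture is exact. Optional
corruptions, applied in acquisition order: a smooth multiplicative bias
field (random low-order 3-D polynomial, mean 1 over the brain mask, with
the stated amplitude attained *inside* the mask — a random polynomial
peaks at grid corners, which no brain occupies) and Rician noise
(|signal + complex Gaussian|, the standard magnitude-MRI model). Raw
intensities are not clipped to [0, 1]: clipping belongs to
preprocessing, mirroring the pipeline order.

Phantoms emulate the *intensity* structure of real T1w data — multimodal
histograms, class overlap under corruption, mean-1 smooth bias — but not
its morphology: no cortical folding, no partial-volume mixture voxels
beyond hard class boundaries, no lesions, no acquisition artifacts.
Passing tests therefore demonstrate the algebra and statistics of the
method, not segmentation performance on clinical images.

## Numerical choices

* **EM initialization** is deterministic: component k starts at the
  (2k−1)/(2K) quantile of the masked intensities, variances at the total
  variance, mixing uniform. Fits are reproducible without a seed; a
  seeded k-means initialization is available for parity with common
  library defaults and reaches the same optimum on separated data.
* **Convergence** requires the relative change in mean log-likelihood to
  stay below `tol = 1e-6` for three consecutive iterations. The
  three-in-a-row rule exists because EM for closely spaced components
  crosses a near-flat ridge where the per-iteration change transiently
  dips (observed at ~1e-5) before accelerating again; a single-shot
  threshold at conventional tolerances stops on that ridge with the two
  brightest components still merged and fitted means off by ~0.1. The
  comparison uses max(|ll|, 1) as the scale so it remains meaningful when
  the mean log-likelihood passes through zero.
* **Posteriors** are computed in log space with a row-wise log-sum-exp;
  extreme likelihood ratios (e.g. e⁻¹⁸⁰⁰) yield exact 0/1 posteriors
  rather than NaN.
* **Degenerate inputs** fail loudly: constant images (P1 = P99), masks
  smaller than 10·K voxels, fewer distinct values than components, zero
  trimmed SD in the robust z-score, and σ = 0 in the original parameters
  at reconstruction (distance undefined).
* **Ties** in the hard class map break toward the lowest component
  index — arbitrary but fixed and tested.
* **Negative perturbed variances** are resampled (≤ 100 tries) then
  clamped to the variance floor; with the default `s_var` this matters
  only for components whose fitted variance is already near the floor.
* **Precision:** volumes are stored as float32 on disk (MRI convention);
  all internal arithmetic is double.

## Reproducibility design

Every random step takes an explicit integer seed and restores the global
RNG state afterwards. Variant i of a master seed uses a counter-derived
sub-seed, so requesting more variants never changes earlier ones, and an
augmentation stream restarted with the same seed replays element-wise
(`augmenting_iterator`, which also caches each volume's fit — the fit
does not depend on the perturbation, so one fit per volume serves any
number of variants; augmentation is a training-time operation only). The
CLI writes a JSON provenance sidecar (seeds, sampled offsets, fitted and
perturbed parameters) next to every output, sufficient to regenerate it
byte-identically.

## Problem sizes in the checks

The packaged verification uses 64³ phantoms for the identity, recovery
and structure-preservation checks, a 50-image collection of 32³ phantoms
for calibration, 40³ phantoms over 10 seeds per amplitude for the
bias-field sensitivity curve, 500 voxels for the scalar-oracle
comparison, and 10⁵ draws for the sampling-law moments — sizes at which
every statistic is stable at the asserted tolerances on a single CPU.

## Known limitations

* K is fixed per fit; no lesion (4th) component, no spatial priors or
  MRF smoothing, no multivariate (multi-sequence) mixtures.
* The method presumes bias-corrected input and the package does not
  reimplement N4-style correction or registration; apply those upstream.
* Augmented intensities are unbounded by default (see `clip`).
* The phantom is a statistical, not anatomical, stand-in — see above.
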