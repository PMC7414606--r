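---
title: "Methods: flow-void quantification, GA growth, and clustered conversion modelling"
author: "ccfv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow-void quantification, GA growth, and clustered conversion modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the
measurement conventions, the statistical models and their assumptions,
the numerical choices, and what the synthetic validation does and does
not establish about real data.

## Scan geometry and units

All en face layers live on a square raster (default 500 x 500 px over
6 x 6 mm), so one pixel is exactly 12 µm across. Angular sizes convert
through the device calibration of 3.5°/mm: the 2° band around the GA
margin is 2/3.5 mm ≈ 571.4 µm, which we round to the nearest pixel,
48 px. Conversions are exact rationals at the default geometry, so the
unit tests assert them without tolerances. Distances between pixels are
Euclidean, centre to centre. The axial dimension (slab definitions such
as "64–400 µm below Bruch's membrane") is carried as metadata only; the
analysis is purely en face.

## Flow-void measurement

A pixel is a flow void (FV) when its compensated CC OCTA intensity falls
*strictly* below `mean − k·SD` of a normative database (default `k = 1`;
ties at the threshold are not FV — "below" is read as strictly below, and
the choice is configurable). Compensation multiplies the angiogram by
`reference / smoothed(structural)`, with a 5-px mean smoothing window and
the gain clipped to [0.5, 2]; the cited compensation approach does not
publish its constants, so all three are exposed as arguments and their
defaults are package choices. Because the gain depends only on the
structural slab, FV% is invariant to arbitrary intensity changes inside
any exclusion mask — a property the acceptance suite checks directly.

Exclusions before computing FV%:

* **Drusen** — elevation map thresholded at `height_cut_um` (default
  15 µm; this cut is *not* a literature constant, only the diameter rule
  is), 8-connected components kept when the equivalent diameter
  `2·sqrt(area/π)·12 µm` exceeds 25 µm.
* **Projection artifacts** — Otsu threshold of the inner-retinal
  angiogram, dilated by one pixel.
* **Baseline GA** — the segmented lesion itself.

The blurred-FV variant convolves the binary FV map with a Gaussian of
σ = 9 px (kernel truncated at 3σ). The source description gives a
"radius" without defining it; we interpret radius as σ and document that
choice here. 9 px is 1.8% of a 500-px image.

## GA segmentation, registration and growth

Atrophy appears bright on the sub-RPE slab (hyper-transmission). The
automatic segmentation is Otsu thresholding, morphological closing with a
3-px disc, hole filling, and removal of components below 0.01 mm² (a
package choice, configurable); a user-supplied override mask — the
analogue of a manually corrected outline — is used verbatim. Lesions
touching the scan border are excluded by default (`allow_border` includes
them), mirroring the primary-cohort convention of restricting to lesions
contained in the 6 x 6 mm field.

Registration estimates a rigid integer translation (search window
±20 px) maximizing the FFT cross-correlation of Otsu vessel masks from
the inner-retinal layers, normalized by the masks' global norms. A peak
below 0.1 is treated as unreliable: the shift falls back to zero with a
warning. Translation-only is a deliberate simplification — vessel
landmarks could in principle drive a similarity transform, but the
synthetic scenes (and short follow-up intervals) only require
translation, and the choice is documented rather than hidden.

Growth is the difference of square-root areas divided by months elapsed,
in µm/month. The square-root transform makes the rate equal to
`v·sqrt(π)` for a disk whose radius grows at `v`, independent of the
baseline radius; the test suite verifies this on rasterized disks to
within 2% rasterization error. When months are not supplied directly
they are computed from visit dates as `days / 30.4375`.

## The conversion model

For every pixel with margin distance `0 < d ≤ 40` px (60- and 80-px
rings are available) and outside all exclusions, the per-eye model is

    logit P(converted) = b0 + b1 d + b2 d² + b3 f

with `f` the FV indicator (or blurred FV fraction). Estimation is by
Firth's bias-reduced logistic regression: maximize
`l(b) + ½ log det I(b)`. Near the margin almost every pixel converts and
far from it almost none does, so quasi-separation is routine; the
Jeffreys penalty guarantees finite estimates where maximum likelihood
diverges. Numerics:

* Fisher scoring on the modified score `X'(y − p + h(½ − p))`, `h` the
  hat values of the weighted design, with step-halving whenever a step
  fails to increase the penalized likelihood.
* Distance is scaled by the ring radius before building the polynomial
  (conditioning); coefficients are mapped back to the per-pixel scale.
* Convergence when the modified-score sup-norm drops below 1e-10
  (maximum 100 iterations). The tight tolerance is deliberate: the
  intercept-only fit must reproduce the closed form
  `p̂ = (k + ½)/(n + 1)` to 1e-8, which a looser score tolerance cannot
  deliver, and Newton's quadratic convergence makes it essentially free.
* Frequency-weighted (aggregated binomial) fits are supported and equal
  the disaggregated fits exactly, since both the likelihood and `I(b)`
  aggregate.

Pixels are the modelling unit; their outcomes are spatially correlated,
and the per-eye model deliberately ignores that. Inference is therefore
*not* read off the per-eye standard errors: each eye is collapsed to its
`b3`, and the cohort-level test operates on those. Both the
degree-2 model (primary) and a degree-1 sensitivity variant are
implemented, since either reading of "second-order polynomial plus
quadratic sensitivity" is defensible; the package exposes `degree` and
takes no further position.

## Clustered inference

Two eyes of one patient share anatomy and exposures, so eye-level
resampling would overstate the evidence.

* **Clustered Spearman.** The correlation is computed over all eyes; the
  null distribution permutes whole patients. With mixed 1- and 2-eye
  patients there is no canonical block permutation; we permute y-blocks
  only among clusters of equal size (composed across size classes), which
  keeps every permuted dataset structurally valid. This scheme is a
  package decision — the source convention is unspecified. Enumeration is
  exhaustive up to 9 clusters, otherwise 10,000 Monte-Carlo permutations
  under a fixed seed (default 20200603).
* **Clustered Wilcoxon.** The signed-rank sum over all eyes, with sign
  flips applied jointly within each patient (2^k patterns, exhaustive up
  to 20 clusters). Zeros are dropped before ranking; midranks handle
  ties; the two-sided p counts the observed arrangement in both numerator
  and denominator, so p > 0 always.

Both tests reduce to their ordinary single-eye versions when every
cluster has one eye, and the suite checks exhaustive and Monte-Carlo
modes against each other and type-I error on simulated clustered nulls.

## The synthetic forward model

`make_eye_scene()` generates: GA foci as disks modulated by low-frequency
radial Fourier noise (multifocal when `ga_foci > 1`); FV patches by
thresholding a smoothed Gaussian random field at the quantile matching
the requested density (optionally distance-dependent); drusen as Gaussian
elevation bumps that also attenuate the CC layer; vessels as random
branching walks, rendered bright in the inner-retinal layer and as
additive projection texture on the CC layer; and hyper-transmission
(bright sub-RPE) inside GA. Follow-up growth converts each ring pixel
independently with probability `plogis(b0 + b1 d + b2 d² + b3 f)` — the
model-faithful mode, chosen so that parameter recovery is well-posed; the
ground-truth conversion table is returned alongside the rendered layers.
Follow-up layers are translated by a small random integer shift so the
registration step is exercised. `make_cohort()` adds a patient-level
latent severity that shifts both FV density (logit scale, loading 0.5)
and the conversion intercept (loading 0.6), inducing within-patient
correlation and a positive FV-growth association across eyes; months
between visits are uniform on 7–16, and the default cohort is 12 eyes
from 7 patients (five contributing both eyes).

Default generator conditions: normative intensity 100 ± 20 (arbitrary
units), FV patch density 0.15, FV depth 2 SD, two GA foci of ~60 px
radius, 12 drusen of ~40 µm peak height, and conversion coefficients
`b0 = 2, b1 = −0.25, b2 = 0.0015, b3 = log(1.33)`. The intercept was set
so that the *ground-truth* square-root-area growth rate at the default
scene is about 21 µm/month over a typical one-year interval, matching
reported GA progression speeds. Note that the *measured* end-to-end
growth rate runs higher than the ground truth: independent per-pixel
conversion produces a speckled front, and morphological closing in the
follow-up segmentation solidifies it, inflating the measured area. Real
atrophy fronts are solid, so this is a simulator artifact to keep in
mind when reading end-to-end numbers; an explicit front-propagation
growth mode would remove it at the cost of an identifiable truth.

What the generator does **not** emulate: OCT speckle statistics and
attenuation physics, eye-motion artifacts, rotation/scale between
visits, foveal sparing, drusen regression, and the empirical spatial
statistics of FV in normal eyes (unpublished; patch geometry is a free
simulation choice). Passing tests therefore demonstrate correctness of
the measurement and inference machinery under a controlled forward
model — not clinical performance on device data.

## Validation design and problem sizes

* Closed-form and grid-search oracles pin the Firth estimator (1e-8 and
  1e-4 respectively); brute-force all-pairs searches pin the distance
  transform and band masks on small grids; pixel counting pins FV%.
* Parameter recovery runs 200 replicate 12-eye cohorts per true odds
  ratio (1.0, 1.33, 2.0) on 128-px scenes with one 18-px GA focus — a
  size chosen so the full 40-px ring fits the scan while keeping the
  study cheap enough to re-run routinely; the median of per-cohort
  median ORs is required to cover the truth within its order-statistic
  confidence interval, and the clustered Wilcoxon type-I rate at the
  null must stay within Monte-Carlo error of 5%.
* The acceptance script (`scripts/acceptance.R`) repeats the recovery at
  60 cohorts per truth and runs one full 500-px, 12-eye cohort end to
  end.

## Known limitations

* Registration is translation-only and integer-valued.
* The automatic GA segmentation is an Otsu + morphology stand-in for a
  grader-corrected outline; it is calibrated only against synthetic
  truth (baseline Dice ≥ 0.95 in tests).
* PNG rasters are written 8-bit; 16-bit data uses TIFF.
* The per-eye model ignores spatial autocorrelation of pixel outcomes by
  design; only the cluster-level tests carry inferential weight.
* Normative statistics default to a simulated 20-subject database; real
  deployments should supply device-matched normative values via
  `pipeline_config(normative = list(mean = ..., sd = ...))`.
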