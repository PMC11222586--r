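---
title: "Screening liver cysts out of CT tumor segmentations with Gaussian histogram fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening liver cysts out of CT tumor segmentations with Gaussian histogram fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystscreen)
```

## The problem

Deep-learning models for liver tumor segmentation are usually trained on
public datasets in which cysts are not annotated. On clinical CT, benign
fluid-filled cysts (HU near water) look much like hypodense tumors, so the
network absorbs them into the predicted tumor label. In radiotherapy
planning a false-positive "tumor" receives prescription dose, so removing
cysts from the prediction matters clinically. `cystscreen` implements a
purely image-feature-based post-processing step: it needs no retraining and
operates only on the predicted mask plus the CT intensities.

## Model and procedure

The working assumption is that each connected region of the predicted tumor
mask contains a single lesion, and that within a lesion the marginal HU
distribution is approximately Gaussian. The pipeline per region:

1. **Region decomposition.** Maximal connected components of the tumor
   label under 26-connectivity (default). 6- and 18-connectivity are
   available, but with anisotropic slices (e.g. 1.5 mm) 6-connectivity
   tends to fragment single lesions.
2. **Histogram.** HU values of the region's voxels binned at 1 HU over
   (−200, 300). Voxels outside the range are excluded (not clamped, which
   would pile mass onto the edge bins) and counted for audit.
3. **Smoothing.** Centered moving average, 5 bins, reflected boundaries.
   Raw per-bin counts are noisy at the several-hundred-voxel scale of small
   lesions; a short linear smoother stabilizes the fit without biasing the
   mean (it is symmetric). Smoothing twice is equivalent to one pass with
   the implied triangular kernel; this is tested numerically.
4. **Gaussian fit.** Nonlinear least squares of
   `f(HU) = A/sqrt(2πS²)·exp(−(HU−M)²/(2S²))` against bin centers vs
   counts (Levenberg–Marquardt, bounds `S ∈ (0.1, 500)`, `M` inside the
   histogram range, moment-based initialization). Counts rather than
   normalized frequencies are fitted; only `M` feeds the decision, so the
   bin-width dependence of `A` is harmless. A least-squares fit to the
   smoothed histogram — rather than maximum likelihood on voxels — is the
   point of the method: pre-smoothing would be meaningless under ML, and
   the fit is what makes the mean robust to stray noise voxels.
5. **Decision.** A region is a cyst iff its decided mean is **strictly
   below 45 HU**. The decided mean is the fitted `M` when the fit converged
   with `R² ≥ 0.5`; otherwise the count-weighted empirical mean. Regions
   with fewer than 64 in-range voxels skip the fit entirely (curve fitting
   on a handful of bins is noise) and use the empirical mean; regions whose
   voxels all fall outside the histogram range decide on the raw voxel
   mean. Every fallback is flagged in the report.
6. **Rewrite.** Cyst-verdict regions are relabeled to the cyst label by
   default (audit-friendly) or to background with `erase_cysts = TRUE`;
   tumor-verdict regions are untouched. The filtered foreground is always a
   subset of the prediction, and refiltering the output is the identity.

The 45 HU threshold sits between the two fitted operating points observed
on clinical data (tumors `M ≈ 91, S ≈ 23`; cysts `M ≈ 17, S ≈ 22`) and is a
configuration default, not a constant: it was derived from per-case fits
and a clinic may retune it. With those presets the two distributions are
~3.3 pooled standard deviations apart, so a correctly fitted mean is far
from the cutoff on either side.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `threshold` | 45 | HU | cyst/tumor cutoff on the decided mean |
| `connectivity` | 26 | – | region decomposition neighborhood |
| `bin_width` | 1 | HU | histogram resolution |
| `hu_range` | (−200, 300) | HU | fit support; covers both lesion classes |
| `smooth_window` | 5 | bins | moving-average width (odd) |
| `min_fit_samples` | 64 | voxels | below: empirical-mean fallback |
| `min_r_squared` | 0.5 | – | below: fitted mean not trusted |

All values are echoed into every `filter_report`, so a decision can be
audited from the report alone.

## The phantom generator

`build_phantom()` emulates exactly the structure the method assumes: a
uniform background (−1000 HU), an ellipsoidal liver of Gaussian parenchyma
(60 ± 10 HU by default — chosen to be separable from both lesion classes,
and configurable), and spherical lesions whose voxel HU are drawn i.i.d.
from per-lesion Gaussians with presets 91 ± 23 HU (tumor) and 17 ± 22 HU
(cyst). Additive acquisition noise (5 HU) applies outside lesions only, so
lesion HU variance is governed solely by the lesion parameters. Sphere and
ellipsoid membership are evaluated on voxel centers in physical mm, so
anisotropic spacing (default 1 × 1 × 1.5 mm) is handled exactly.
`simulate_prediction()` then produces the failure mode the filter exists
for: truth cysts merged into the tumor label, optionally with seeded
per-region boundary jitter (dilation/erosion up to a given radius) to mimic
contour error.

What the phantom deliberately does **not** model: spatial texture within
lesions (the decision rule only uses the marginal HU distribution, so
i.i.d. sampling makes the model's assumption literally true), partial
volume, beam hardening, contrast phases, calcifications, and lesions
touching each other. Passing on phantoms therefore shows the
post-processor is correct *given its assumptions*; it does not certify
performance on clinical CT, where fitted means sit closer to the cutoff
and mixed or calcified regions occur.

Phantom construction is bit-reproducible given the spec and seed: sampling
order is fixed and every stochastic operation takes an explicit seed (no
global RNG state is left behind).

## Evaluation metrics

`dsc()` implements the Dice similarity coefficient
`2|A∩B|/(|A|+|B|)` with the conventions empty-vs-empty = 1 and
empty-vs-nonempty = 0. `hausdorff()`/`hd95()` compute surface-to-surface
distances: surfaces are voxels whose 6-neighborhood leaves the structure
(image borders count as background), mapped to physical mm. Directed
distances are evaluated with an exact separable Euclidean distance
transform, and HD95 takes the maximum of the two directed 95th percentiles
(linear-interpolation percentile), mirroring how the exact Hausdorff
distance symmetrizes by max; the pooled-percentile variant used elsewhere
in the literature is available via `method = "pooled"`. Tests require exact
agreement with a brute-force all-pairs oracle. `compare_cases()` produces
the per-case table with mean/sd/min/median/max aggregates and a two-sided
paired t-test on per-case differences; all-zero differences report P = 1
by convention.

## The multi-scale loss

`total_loss()` is a framework-independent reference for deep supervision:
per scale `0.5·CE + 0.5·soft-Dice`, summed over K = 4 scales with uniform
1/K weights (C = 3 classes by default). Design choices that the formula
leaves open, fixed here and recorded in `loss_config()`:

* **CE reduction** is the per-voxel mean, keeping scales of different voxel
  counts comparable.
* **Activation.** The CE term is written in softmax form, but the
  dual-structure output (tumor inside liver) requires sigmoid activation;
  with sigmoid, CE is scored as per-channel binary cross-entropy (mean over
  voxels and channels). Both are implemented; `activate()` tags its output
  so the right form is used.
* **Soft Dice** uses `Σ y·p` for the intersection with `epsilon = 1e-5`
  added to the denominator only. Consequence: a class absent from both
  target and prediction scores dice 0 (not 1) at that scale, so "perfect
  prediction ⇒ loss ≈ 0" holds when every class is present at every scale —
  the practical case for liver/tumor volumes; the coarsest supervision
  scales of real crops retain both structures.
* **Target pyramids** are built by per-block majority vote with ties to the
  smallest label id (deterministic, label-order independent); non-divisible
  extents are padded by edge replication.
* `scale_loss_grad()` provides the analytic gradient in the probabilities,
  checked against central finite differences.

## Numerical choices and degenerate inputs

* Optimizer: `ftol = ptol = 1e-8`, at most 10,000 function evaluations;
  failure to converge is a *reported state* (empirical-moment fallback),
  never an exception that kills the pipeline.
* Histograms with fewer than 3 nonzero bins raise a classed degenerate-fit
  condition that the filter catches via its fallback chain.
* An empty prediction filters to itself with an empty report.
* Region ties in the size ordering break on the smallest linear voxel
  index; ids are always 1..k by descending size.
* Distance-transform arithmetic replaces +Inf by 1e30 to keep the
  lower-envelope recursion finite; exactness on realistic extents is
  unaffected and tested against all-pairs distances.
* Morphological dilation claims background voxels only; collisions with
  other labels are counted and reported, never overwritten. The discrete
  2 mm ball reaches only √3 mm along voxel diagonals, so dilated volumes
  undershoot their continuum counterparts by several percent — the tests
  pin the operation to a brute-force nearest-source oracle instead of the
  continuum volume.

## Problem sizes used in validation

The test suite exercises 64×64×44-voxel phantoms (1 × 1 × 1.5 mm) with
two tumors and two cysts per case — large enough that every lesion clears
the fit-sample floor by an order of magnitude, small enough to keep a
40-replicate end-to-end study quick on a laptop. Parameter-recovery checks
draw 50,000 samples per preset, where the fitted `M` and `S` land within
1 HU of the generating values across seeds. Lesion layouts keep a 4 mm
surface clearance so that voxelized lesions never fuse into one connected
region, which would violate the one-lesion-per-region assumption (mixture
regions are out of the model's scope by design).

## Known limitations

* The decision threshold and HU presets come from per-case clinical fits;
  they are defaults to be audited, not population truths.
* A region containing both tumor and cyst tissue gets a single Gaussian
  and a single verdict; multi-component mixtures are out of scope.
* Calcified lesions (high HU) are always kept; the method has no rule for
  them.
* Phantom validation certifies the post-processor's logic, not clinical
  performance (see the phantom section above).
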