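---
title: "Models and methods behind datspect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind datspect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented by the package, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
choices that were genuinely open.

## 1. Quantification model

A DAT-SPECT scan is reduced to putamen specific binding ratios in four
steps.

**Stereotactical normalization.** A 12-parameter affine (3 translations
in mm, 3 rotations, 3 zooms, 3 shears, composed `T R Z S`) maps the
native scan into a 2 mm isotropic template space. The transform is found
by minimizing the sum of squared residuals between the transformed scan
and the best linear combination of the template(s), restricted to a
template-space head mask (brain plus scalp, cerebellum excluded) times a
200 mm source cube centered at the scan's center of mass. The template
coefficients (plus a constant offset column) are solved in closed form by
weighted least squares inside every cost evaluation, so the outer
optimization runs over the 12 geometric parameters only. With a single
template the "combination" degenerates to one scale coefficient plus
offset, which makes the cost invariant to the global intensity
calibration of the scanner — the reason no intensity normalization is
needed before registration.

**Intensity scaling.** The normalized scan is divided by the 75th
percentile of its intensities in a reference region (whole brain without
striata, thalamus/brainstem, cerebellum, ventricles), giving a
distribution volume ratio (DVR) image; nondisplaceable background tissue
sits at DVR about 1.

**Regional readout.** Two estimators per hemisphere:
hottest-voxels (HV) SBR, the mean of the n hottest DVR voxels inside a
deliberately oversized unilateral putamen mask with n fixed by a 10 ml
total volume (1250 voxels at 2 mm; ties at the n-th value resolved by
descending value in deterministic index order), and the anatomical-ROI
SBR, the plain DVR mean in a tight putamen mask. Both are reported as
`SBR = DVR - 1`, with the subtraction applied after averaging (identical
to voxelwise subtraction for means). Left, right, their minimum and
their mean are recorded, plus the DET of the normalization transform.

**Cohort statistics.** The cohort SBR histogram (bin width 0.1, half-open
bins anchored at 0, negative bins allowed) is fitted by the sum of two
Gaussians by Nelder-Mead least squares; the separation of the reduced and
normal components is summarized by the pooled-SD effect size `d` and the
SD-weighted midpoint cutoff `c`. Agreement between pipeline variants is
quantified by 2x2 cross-tables, Cohen's kappa (large-sample SE), and the
stability of `d` by refitting on random 90% subsamples.

## 2. Registration: parameters and numerical choices

* **Similarity metric** — weighted SSD with closed-form coefficient fit.
  The normalization software this mirrors matches templates by least
  squares; mutual information would be overkill within one modality.
* **Pyramid** — extra smoothing of 8, 4, 0 mm FWHM, cost evaluated on
  every 2nd in-mask template voxel. Nelder-Mead at the two coarse levels
  (robust far from the optimum, no gradients near plateau edges), then a
  finite-difference BFGS at the finest level with one restart. A pure
  12-parameter simplex reliably stagnates 2-4% away in DET: we verified
  cost(truth) << cost(simplex result) on noise-free self-consistent
  phantoms, which is why the quasi-Newton polish exists.
* **Interpolation-blur compensation** — trilinear resampling smooths the
  *moving* image by on average `2.355 * voxel / sqrt(6)` mm FWHM but not
  the grid-aligned templates; left uncompensated this biases the zooms
  upward by about half a percent per axis. The templates are therefore
  smoothed by that amount (in quadrature with the pyramid level). The
  value was calibrated so that noise-free self-consistent registration is
  unbiased.
* **Regularization** — quadratic penalty `lambda (||log zoom||^2 +
  ||shear||^2)`, default `lambda = 0.005` on the variance-normalized
  cost. It vanishes at identity (self-registration stays unbiased), is
  negligible at true zooms of 0.9-1.1, and stabilizes the fit when the
  data are uninformative.
* **Initialization** — translation from aligning the scan's intensity
  center of mass with the head-masked template's; unit zooms; seedless
  and deterministic.
* **Degenerate template sets** — the coefficient solve carries a minimal
  Tikhonov term (1e-8 relative) because painted scalp template variants
  share one scalp-shell basis function and are exactly collinear. The
  fitted *image* and the transform are unaffected by this null space;
  individual coefficients are only identifiable for linearly independent
  template sets, and the tests assert coefficient recovery on such a
  subset.
* **Failure handling** — fewer in-mask voxels than free parameters is an
  error; non-convergence at the finest level flags the result rather
  than failing silently.

## 3. Template construction

Templates are built by iterated normalize-average passes: normalize every
scan to the current target (single-template mode), scale to DVR, average
voxelwise ("soft mean"), three passes in total (initial pass plus two
repeats). The normal-uptake template is symmetrized at the midsagittal
plane (`0.5 (x + flip(x))`, an exact flip fixed point); moderate-deficit
scans are flipped so the deficit is right-lateralized before averaging
(ties unflipped), and the left variant is the exact mirror of the right;
the strong template is averaged as-is — whether mixed-side strong scans
should also be reoriented is left open by the source procedure, and this
implementation averages as-is. The historical bootstrap target is not
available, so the initial target defaults to the noise-free painted
normal phantom (any user NIfTI can substitute). Scan selection is by
explicit id lists rather than an alphabetical-PACS convention.

For simulated experiments the eight-template set is painted directly from
the phantom anatomy (`paint_template_set()`): category prototypes at
worse-side putamen SBR 1.9 / 0.66 / 0.28 (normal / moderate / strong,
matching the reported template source scans), blurred by the PSF; this
bypasses dozens of registrations while preserving the set's structure.

## 4. The phantom: what it emulates, and what it does not

The generator paints ellipsoidal anatomy on a 54 x 64 x 50 grid of 2 mm
voxels: brain background at DVR 1, bilateral putamen (15 ml each) and
caudate, ventricles at DVR 0.5, a thalamus/brainstem placeholder,
cerebellum, and an optional scalp shell at DVR 1.2-2.0 standing in for
reconstructions without attenuation/scatter correction. Scans are blurred
with a 7 mm FWHM Gaussian PSF (a typical reconstruction post-filter),
given additive Gaussian noise truncated at zero (default SD 5% of
background), mapped to a native 2.5 mm grid through the inverse of a
random affine (translations within 10 mm, rotations within 10 degrees,
zooms 0.9-1.1, shears within 0.05), and multiplied by an arbitrary global
intensity scale in [0.5, 2].

Subjects are drawn from a two-component mixture of the minimum putamen
SBR — reduced: Gaussian(0.58, 0.15), normal: Gaussian(1.57, 0.32),
truncated at SBR > -0.5 to keep DVR positive, reduced fraction 0.449 —
the structure estimated for the minimum HV putamen SBR under
multi-template normalization in a large clinical cohort. The worse side
is uniform left/right; the better hemisphere is higher by a fixed 0.2
(reduced) or 0.05 (normal); the caudate runs above the same-side putamen
by 0.5 (reduced) or 0.1 (normal), the rostrocaudal gradient of
Parkinson-typical loss. Reduced subjects additionally carry striatal
ellipsoids shrunk to 90% of the semi-axes, and the reduced *templates*
are painted with the same shrinkage: this is the template-mismatch
geometry that lets a normal-uptake single template stretch reduced brains
(inflated DET) while the matched reduced templates do not.

Deliberate departures from clinical reality, and their consequences for
what a green test establishes:

* anatomy is ellipsoidal and the brain about half natural linear scale;
  nothing about absolute mask volumes beyond the stated ones transfers;
* the putamen is painted at 15 ml (real putamina are nearer 5-10 ml) so
  that the 10 ml hottest-voxels volume nests inside the structure and
  partial-volume bias stays below 15% at the 7 mm PSF — with real
  anatomy, HV values underestimate true binding much more strongly;
* noise is additive Gaussian on the reconstructed image, not
  projection-domain Poisson through a reconstruction; camera- and
  collimator-specific effects are absent;
* the painted scalp shell is geometrically identical across templates
  (hence their exact collinearity, section 2);
* simulated cohorts therefore validate *recovery* (transforms, SBR,
  mixture parameters) and *directions* (multi-template normalization
  separates better and stretches reduced brains less than a single
  normal template), not the published clinical magnitudes.

## 5. Two-Gaussian fit: initialization and degeneracy

Least-squares fits of a six-parameter double Gaussian need a start; the
default takes the two largest local maxima of the histogram with SD 0.2,
plus two fallback starts from weighted quantiles, keeping the best SSE
after a restarted Nelder-Mead (the `fminsearch` idiom; SDs enter through
absolute values). Components are relabeled so M1 <= M2. A
`single_component` flag marks fits where the second component is not
identifiable — negligible amplitude, collapsed means, or a mean outside
the histogram support (ghost components absorb nothing yet inflate `d`).
Downstream consumers should treat flagged fits as one-component data.
Values at the cutoff classify as "normal" (pinned tie rule).

## 6. Interfaces and defaults worth knowing

| parameter | default | meaning |
|---|---|---|
| `volume_ml` | 10 | hottest-voxels volume per hemisphere |
| reference quantile | 0.75 | DVR scaling percentile |
| `bin_width` | 0.1 | SBR histogram bin |
| `psf_fwhm_mm` | 7 | phantom reconstruction blur |
| `noise_sd` | 0.05 | phantom noise, fraction of background |
| `striatum_atrophy` | 0.9 | striatal shrinkage of reduced subjects |
| `lambda` | 0.005 | zoom/shear regularization weight |
| `scalp_frac` | 0.3 | simulated scans with scalp signal |

Volumes are NIfTI-1 (`.nii`/`.nii.gz`, sform affine; masks as uint8);
tables are CSV; summaries and run configs are JSON; every experiment
artifact embeds the seed and a config hash. Known limitations: affine
normalization only (no warps), 3D single-frame volumes only, and the
minimal NIfTI reader supports the common scalar datatypes only.
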