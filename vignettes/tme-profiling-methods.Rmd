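---
title: "Methods: automated 3D profiling of the tumour microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated 3D profiling of the tumour microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `tmeprofiler`, in the spirit of a methods section: what each stage
assumes, which knobs matter, and what the synthetic test-bench does and
does not demonstrate about real data.

## Coordinate and unit conventions

All volumes are arrays in (Z, Y, X) axis order. Voxel indices are 0-based
in every user-facing table and CSV, and a voxel's physical position is its
centre, `index * spacing`, so voxel (0, 0, 0) sits at the physical origin.
Spacing is anisotropic, given in μm per voxel as (z, y, x); all distances,
centroids and volumes downstream are in physical μm. No operation
transposes axes silently. TIFF files carry no trustworthy spacing metadata,
so spacing is a mandatory argument for TIFF input; HDF5 datasets store it
in an `element_size_um` attribute (ZYX), which an explicit argument
overrides. Binary masks serialize as 8-bit TIFF with foreground 255;
float-valued derived volumes (probability maps) go to HDF5, which
round-trips exactly.

## Pixel classification

Whole-organ LSFM stacks cannot be segmented by a global intensity
threshold: autofluorescent bronchi and vessels are brighter than genuine
signal in deep tissue, and axial bleed-through ("signal leakage along Z")
mimics real objects below bright colonies. The classifier therefore learns
four classes — `signal`, `z_leakage`, `autofluorescence`, `background` —
from sparse voxel annotations.

**Features.** Six filter families over preset scales: Gaussian smoothing at
σ ∈ {0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10} px and the other five at
σ ∈ {0.7, 1.0, 1.6, 3.5, 5.0, 10} px, which expands in 3D to
7 + 3·6 + 2·6·3 = 61 features (the two eigenvalue families contribute three
sorted eigenvalues per scale). σ is in pixel units applied isotropically in
index space; an `anisotropy_correction` flag instead divides σ per axis by
the spacing ratio when a physically isotropic footprint is wanted. Scales
are stated in the source workflow only as ranges ("from 0.3 px to 10 px"),
so the preset grid above — the standard scale set spanning exactly those
ranges — is adopted. Two further conventions are not derivable from the
stated ranges and are fixed here: the difference-of-Gaussians inner ratio
is 0.66 (`blur(σ) − blur(0.66σ)`) and the structure tensor uses inner scale
σ with outer (integration) scale σ/2. Derivative kernels are sampled
Gaussian derivatives renormalized to be exact on linear and quadratic
ramps; boundaries are handled by reflection. Filters run as separable 1-D
convolutions in compiled code.

**Classifier.** A random forest (default 100 trees), the default classifier
family for this kind of interactive pixel classification, with
class-balanced case weights so sparse artifact classes are not swamped.
Training uses the feature vectors at annotated voxels only; annotations are
sorted by voxel index before fitting so the model is invariant to
annotation order, and a seed parameter makes training and prediction
deterministic. The interactive annotate–evaluate–reannotate loop of the
original workflow is a human process; here annotations are an input, not a
product.

**Binarization.** A voxel is foreground when `P(signal) ≥ t` with t = 0.5
by default (inclusive at the boundary, matching the ECDF convention used
throughout); arg-max over the four classes is available as an alternative
mode. The threshold value is not stated in the source workflow; 0.5 is the
natural default for a probability map and is recorded in the mask's
provenance.

## Object extraction

Connected components use 26-connectivity by default: with 10 μm optical
sections and ~6.5 μm pixels, 6-connectivity splits structures that touch
diagonally across the coarse axis. Components are labelled canonically in
raster-scan order of their first voxel, so labellings are reproducible.
The centroid is the unweighted centre of gravity of the binarized object —
the source computation ran centre-of-mass on binary images, which makes
intensity weighting moot; an intensity-weighted option exists but is off by
default. Volume is voxel count × voxel volume. No object-size filter is
applied by default (`min_voxels = 1`), because no minimum colony size is
stated for the original counts; the knob is exposed for users who need one.

## Spatial statistics

Minimal distances are 3D Euclidean distances in μm. Two query modes exist:
centroid → nearest foreground voxel centre of a target mask (used for
colony-to-vessel distances; this is what a centre-of-gravity versus
classified-signal computation measures — distance to the nearest classified
voxel, not to an object surface), and centroid → nearest target centroid
(used for colony-to-colony co-localization). The query runs on a kd-tree
built over target points; candidate distances accumulate in a fixed
dz² + dy² + dx² order so results are bit-identical to an exhaustive scan,
which the tests verify on random phantoms.

The ECDF is the right-continuous step function `F(x) = #{d ≤ x}/n`; all
threshold comparisons in `fraction_within`, `band_fraction` (lo < d ≤ hi)
and `colocalization` are inclusive at the upper boundary for consistency
with it. Co-localization uses the centroid-to-centroid rule with a 20 μm
default threshold; whether the original rule measured centroid-to-centroid
or edge-to-centroid is ambiguous in its one-sentence definition —
centroid-to-centroid is implemented because the definition names the
"centre of gravity of other cells", and the alternative is deliberately not
guessed at.

Density curves are Gaussian KDEs evaluated on a uniform grid over
[0, 1.1·max d]. The bandwidth defaults to Scott's rule, `sd(d)·n^(−1/5)`,
and is always echoed in the output because the original density plots do
not state their estimator. Since distances live on the half-line, kernel
mass leaking below zero is handled by renormalizing the evaluated curve to
integrate to 1 over the grid (trapezoid rule); modes are strict local
maxima of the evaluated curve, with a floor at 0.1% of the peak that
rejects numerical ripples in the far tails of the FFT-based evaluation.

## Segmentation validation

Automated masks are scored against reference masks with Sørensen–Dice,
Jaccard, and Szymkiewicz–Simpson (overlap) coefficients, voxelwise on whole
volumes, with an optional per-Z-slice mode. Conventions for degenerate
inputs: two empty masks score 1 on all three coefficients (perfect
agreement on emptiness, avoiding NaN when a class is absent from both
masks); exactly one empty mask scores 0. The identities
`dice = 2J/(1 + J)` and `jaccard ≤ dice ≤ overlap` are enforced by tests on
random mask pairs.

## Estimation statistics

Group comparisons report the effect size as a bootstrap 95% confidence
interval of the mean difference: each group is resampled with replacement
`n_boot` times (default 5000), the difference of resampled means forms the
effect-size distribution, and the percentile interval is reported. The
percentile flavour (rather than BCa) is the simplest faithful reading of a
"resampled mean difference distribution", and the CI method is echoed in
the output metadata. Significance testing uses the unpaired t-test with
Welch's correction, delegated to `stats::t.test`. Calibration is verified
by simulation: type-I error 0.05 ± 0.02 under the null (2000 replicates,
n = 20 per group) and 95% CI coverage of a true difference δ = 1 within
95% ± 3% (500 replicates, n = 30 per group, 2000 resamples).

## The synthetic phantom

No raw image volumes are publicly deposited for the original whole-lung
experiments, so the test-bench is a generator of multi-channel phantoms
with exact ground truth. It emulates the geometry the pipeline must
recover, not the optics:

* **Colonies** (cancer channel): spheres in physical space (ellipsoidal in
  voxels under anisotropic spacing) with a flat core and a Gaussian
  shoulder whose half-maximum sits exactly at the labelled radius, so the
  label boundary is unambiguous and the centre intensity equals background
  + amplitude exactly when noise is off. Radii are drawn from a range or
  pinned at user-given centres for designed-geometry tests.
* **Vessels** (vessel channel): persistent-random-walk centrelines dilated
  to a physical radius, anisotropy-aware; waypoint polylines can be pinned.
* **Puncta** (platelet/macrophage-like channel): small spheres.
* **Z-leakage**: below a stated fraction of colonies, intensity decays
  exponentially along +Z over a configurable decay length within the
  colony's footprint — the axial bleed-through class.
* **Autofluorescent tubes**: added to *all* channels, as bronchi and
  vessels appear in every real channel.

Per channel every voxel carries exactly one truth class with precedence
signal > leakage > autofluorescence > background. Noise is Poisson shot
noise on the noiseless image plus additive Gaussian read noise, the
standard fluorescence camera model, so SNR can be dialled for classifier
stress tests. Object placement is rejection sampling with a minimum
centre-to-centre separation (sum of radii + 2 voxels) so ground-truth
component counts are unambiguous; an exhausted retry budget raises an
error naming the crowded channel. Identical seeds give bit-identical
phantoms.

**Default conditions.** The reference phantom is 64 × 128 × 128 voxels at
(10, 6.5, 6.5) μm — deliberately desk-scale and anisotropic — with 20
colonies (radius 15–40 μm, amplitude 2000 counts), 2 vessel trees (radius
12 μm, amplitude 1500), 30 puncta (radius 8 μm, amplitude 1200), leakage
under half the colonies (30% of the colony amplitude, decay length 5
voxels), 2 autofluorescent tubes (amplitude 800), background 100 counts,
and read noise σ = 20. Amplitudes are ordered so the four classes are
separable but not trivially so (autofluorescence at 800 sits close to the
brightest leakage at 600); they are free parameters of the phantom, not
estimates of any real instrument.

**What passing does and does not show.** The phantom has piecewise-smooth
objects, stationary noise, and no point-spread-function blur, depth
attenuation, stitching seams or staining gradients. Recovery on the phantom
demonstrates that the implementation is correct and internally consistent
— exact distance queries, exact geometry recovery, calibrated statistics —
not that the default classifier settings transfer to any particular
instrument; on real data the annotation effort and binarization threshold
remain the user's responsibility.

## Problem sizes and determinism

The shipped tests run the full default phantom (~10⁶ voxels, 61 features)
through training, prediction and the complete pipeline twice to verify
bit-identical re-runs; designed-geometry tests use a 52 × 96 × 32 phantom
whose colony-to-vessel distances are exact by construction. A single global
seed derives per-stage seeds by hashing the stage name, so any stage can be
re-run in isolation with stable randomness; all derived seeds stay below
2³¹.

## Known limitations

* The classifier is trained per channel; no cross-channel features.
* Distance-to-mask measures proximity to classified voxels, not to object
  surfaces; for objects larger than the structures of interest the two can
  differ by up to the object radius.
* Touching colonies are not split (no watershed); counts on dense data are
  counts of connected clumps.
* The phantom does not simulate optics (PSF, attenuation) or clearing
  chemistry; see above for what that implies about test coverage.
* Proprietary microscope formats (Imaris, CZI) and terabyte-scale on-disk
  processing are out of scope; inputs are multi-page TIFF or HDF5 volumes
  that fit in memory.
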