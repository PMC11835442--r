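---
title: "Models and methods behind wmhpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wmhpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wmhpath` studies how FLAIR signal in periventricular white matter relates
to quantitative histopathology: myelin staining (Luxol Fast Blue),
axonal-damage immunolabelling (phosphorylated neurofilament medium chain,
NfM), and polarized light imaging (PLI). This vignette is the package's own
account of its models, the parameters that matter, the rules it had to
declare where the underlying laboratory protocol is ambiguous, and what its
synthetic validation does and does not show.

## The synthetic phantom

Real post-mortem MRI-histology material is not publicly distributable, so
the package ships a generator whose outputs have a fully known statistical
structure. A subject is a concentric 2D slice: a ventricle hole, a
periventricular WMH ring, NAWM, and a GM rim, rasterised at the native
resolution of each modality (FLAIR 500 µm/px, T1 400 µm/px, histology/PLI
20 µm/px by default; tests and the acceptance script use 50–100 µm histology
grids and 30–32 px MRI slices to keep runtimes in seconds — stated here as
the package's chosen problem sizes).

The noiseless FLAIR field is piecewise constant
(`background < GM < NAWM < WMH core`, default 20/80/100/160) except for a
radial ramp that rises from the NAWM plateau, across the WMH/NAWM boundary,
to the hyperintense core. Two widths control it: `wmh_gradient_width_um`
(the decay inside the WMH ring) and `nawm_ramp_um` (how far the elevated
signal reaches into the NAWM border zone). The border-zone extension is
deliberate: the scientific premise under test is that pathology grades
continuously from NAWM into the lesion core, so the planted gradient must
cross the ROI boundary; setting `nawm_ramp_um = 0` recovers a perfectly
flat NAWM (and is unit-tested as such). Ring radii get small per-subject
log-free jitter (`radius_jitter_frac`) so a cohort is not twelve copies of
one geometry.

Every pathology field is coupled linearly to the *noiseless* FLAIR field:

- stain amount (OD units) `= coupling_intercept + coupling_slope × FLAIR`,
  clipped at zero (default intercept 1.0, slope −0.005, i.e. NAWM ≈ 0.5 OD
  and WMH core ≈ 0.2 OD);
- PLI retardance `= intercept + slope × FLAIR` clipped into [0, 1]
  (default 0.9 and −0.004).

A negative slope plants the inverse FLAIR-pathology relation; slope 0 is
the null generator used for calibration. The hypertension group receives
additive shifts (`group_effect`: less LFB, more NfM). Noise models are the
simplest with closed-form checks: additive Gaussian on MRI and PLI
intensities, multiplicative log-normal on stain amounts.

Stained sections are rendered in the histology frame through the
Beer–Lambert forward model (`I_c = 255·10^(−amount·v_c)`) with LFB as a
single blue-absorbing vector and NfM as a DAB + constant-haematoxylin
mixture; the stain vectors are package constants (standard deconvolution
values for haematoxylin and DAB) and user-overridable. The histology frame
differs from the MRI frame by a configurable rotation/anisotropic-scale/
shear/translation affine (default 7°, 1.05/0.95, translation a few hundred
µm) so registration is never trivial; landmark pairs are exact images of
random points under that affine plus Gaussian jitter of stated SD.

## Segmentation network

The four-class tissue segmentation (background, GM, NAWM, WMH) uses an
ensemble of small U-Nets written directly in R (im2col convolutions on
BLAS, 3×3 kernels, 2×2 max-pooling, nearest-neighbour upsampling with skip
concatenation, a 1×1 output head). Defaults — depth 3, 8 base channels,
2-channel input (T1 resampled onto the FLAIR grid, where the truth labels
live), Adam at 2·10⁻³, 40 epochs, loss = cross-entropy + soft-Dice — were
chosen so that training a member on eight 64×64 slices takes about a minute
of CPU. T1 is resampled to the FLAIR grid (not the reverse) because the
lesion definition, and hence the reference labels, are FLAIR-native;
resampling labels would corrupt the ground truth with interpolation
artefacts. Augmentation (axis flips, right-angle rotations, per-channel
gain/offset jitter) is applied on the fly, geometrically identical for
images and labels. All randomness (member initialisations, shuffling,
augmentation) derives from one seed, so training is bit-reproducible.
Ensemble prediction is the arithmetic mean of member softmax maps; argmax
ties break toward the lowest class index, so a tie never invents lesion.

## Intensity grading

WMH and NAWM are separately divided into k = 3 segments by k-means on FLAIR
intensity, labels assigned by ascending centroid rank (segment 1 = lowest
signal). The solver runs k-means++-seeded Lloyd restarts, then exploits the
1-D structure: on small inputs (≤ 512 values) the exact contiguous-partition
dynamic program replaces the heuristic answer; larger inputs get a
split-boundary descent. Nearest-centroid ties go to the lower segment
(deterministic, conservative toward "less abnormal"). Grading is
per-subject by default, matching per-slide heatmaps; pooling across
subjects is a caller decision (cluster on the concatenated values and pass
the centroids to `assign_segments()`).

## Registration and the partial-volume guard

The histology section is always the fixed reference; MRI moves. The affine
is the least-squares minimiser over paired landmarks in physical µm
coordinates (exact for 3 non-collinear pairs; a warning below 10 pairs
mirrors the manual protocol's minimum). Warping is inverse-mapping:
bilinear for intensities, nearest-neighbour for labels, `NA` outside the
source field, and those pixels never enter any aggregate.

One analysis rule had to be added on top: bilinear resampling of 500 µm MRI
onto a 20–100 µm histology grid smears CSF and GM signal up to one MRI
voxel into the adjacent white matter. Left alone, that partial-volume rim
forms its own low-intensity cluster, capturing "segment 1" at the ventricle
wall — where the planted pathology is at its *worst* — and inverting the
3-vs-1 contrast. `process_subject()` therefore excludes white matter pixels
within one FLAIR voxel (`pv_guard_um`, settable, 0 disables) of any
non-white-matter label from the registered FLAIR values, the grading and
the ROI votes. Stain and PLI metrics are unaffected — the pathology there
is real; only the MRI value is contaminated.

## Stain and PLI quantification

Optical density uses ε = 1 inside the log to keep saturated pixels finite;
amounts are `M⁻¹·OD` with negative values clipped and the clipped fraction
recorded. The positivity threshold is declared as the midpoint of the mean
amounts of a positive control region and a background region (the
underlying protocol states only that thresholds came from control regions
and were checked per section; the midpoint is this package's rule, and an
`override` honours per-section manual values). Two percent metrics are
implemented because "intensity (%)" is ambiguous: `area` (positive-pixel
fraction × 100, the default) and `intensity` (thresholded amount normalised
to the 99th-percentile positive amount). The mode is recorded on the
output. Note a structural property of the midpoint rule: when an ROI sits
entirely above threshold, the area metric saturates at 100 and carries no
within-ROI gradient — this is why gradient analyses in the examples and
acceptance runs use the intensity mode.

PLI stacks are fitted per pixel by the discrete Fourier estimator of the
standard rotation sinusoid; on equally spaced angles this equals the
least-squares fit (tested against a generic LS oracle). Retardance is
reported on a 0–100% scale as the myelin-density proxy. The dispersion /
microstructural-integrity measure of dedicated PLI pipelines is not fully
specified by its citations, so the package declares one: local circular
variance `V` of doubled directions in an odd window (default 5 px),
integrity = 100·(1−V). It is exact in the limiting cases (coherent field →
100; uniformly spread or orthogonally mixed orientations → 0) and is
labelled a declared stand-in in outputs.

## Blocks and statistics

Co-registered images are tiled into 400 µm × 400 µm (0.16 mm²) blocks —
the block side must divide into whole pixels; trailing partial rows/columns
are dropped and counted. A block is included when at least half of its
pixels contain tissue (strictly-less-than-50% excluded; exactly 50% kept).
ROI and segment are pixel-majority votes (ties: NAWM, lower segment);
blocks dominated by GM/background are dropped.

Statistics treat blocks as independent observations, mirroring the
voxel-wise design (a subject-level random-intercept model would be the
refinement, and is out of scope). ANOVA is a Type II general linear model
(`car::Anova` behind the package surface) with Bonferroni correction over
tested effects; a zero-variance response returns F = 0, p = 1 rather than
an error. Segment contrasts are two-group F tests with m = 3 Bonferroni.
α conventions: 0.05 for ANOVA, 0.01 for correlations.

## What the synthetic validation shows — and does not

Passing tests show that each stage implements its stated mathematics
(oracle-matched), that the stages compose (a planted negative gradient is
recovered as negative block-level correlations and ordered segment means
through registration, deconvolution and aggregation), and that the testing
battery is calibrated (null generator, 200 seeds, false-positive rates
within binomial bounds of α). They do not show performance on real tissue:
the phantom has no folds, tears, staining artefacts, anatomical asymmetry,
scanner bias fields, or 3D slice-matching error, and its noise is idealised.
Dice ≥ 0.95 on phantoms says the trainer works, not that the tiny network
segments real FLAIR. Numerical edge rules are fixed and tested: argmax and
nearest-centroid ties to the lower index, the 50% inclusion boundary kept,
NA propagation from out-of-field warps, ε = 1 in the OD transform.

## Repository shape

Images (slices, stacks, probability maps) are matrix/array S3 objects, as
in the field's image packages; everything tabular — landmark sets, block
tables, summaries, test results — is tibble-first so calls compose with
dplyr, with `tidy()`/`glance()` on fitted objects and `autoplot()` on
heatmaps.
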