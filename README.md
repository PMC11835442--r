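# wmhpath

Voxel-wise correlation of MRI signal with quantitative histopathology in
periventricular white matter.

## The problem

White matter hyperintensities (WMH) on FLAIR MRI are the imaging hallmark of
cerebral small vessel disease, but they are only the visible tip of a
continuum: normal-appearing white matter (NAWM) around them already harbours
myelin and axonal damage. Establishing that continuum requires registering
post-mortem 2D MRI slices onto stained histological sections and polarized
light imaging (PLI) maps, and then asking, block by block, how FLAIR signal
relates to myelin (Luxol Fast Blue, PLI retardance), axonal integrity
(phosphorylated neurofilament, NfM) and fiber-orientation dispersion.

`wmhpath` implements that analysis end to end for R users:

- **Synthetic phantom generator** — concentric 2D "subjects" (ventricle →
  WMH with a radial FLAIR decay ramp → NAWM → GM rim) with a planted linear
  coupling between FLAIR signal and every pathology field, plus a known
  MRI-to-histology affine and landmark pairs. Every downstream stage has a
  recoverable ground truth.
- **Segmentation** — a compact, CPU-trainable U-Net ensemble (pure R, im2col
  convolutions, Adam, cross-entropy + soft-Dice loss) mapping (T1, FLAIR)
  stacks to {background, GM, NAWM, WMH}, with probability averaging across
  members and per-class Dice evaluation.
- **Intensity grading** — k-means (k = 3) on FLAIR signal inside each white
  matter ROI, yielding ordered segments 1 (lowest signal) to 3 (highest);
  exact on small inputs via a contiguous-partition dynamic program.
- **Registration** — least-squares 2D affine from ≥ 10 manual landmark pairs
  (micrometre coordinates), inverse-mapping warp of images (bilinear) and
  label maps (nearest-neighbour) onto the histology reference grid.
- **Stain quantification** — Beer–Lambert colour deconvolution
  (`OD = -log10((I+1)/255)`, amounts `= M^-1 OD`), control-region
  positivity thresholds, and percent metrics (positive-area or normalised
  intensity).
- **PLI quantification** — Fourier fit of the rotation-stack sinusoid
  `I(ρ) = (I0/2)(1 + r sin(2ρ − 2φ))` per pixel, giving transmittance,
  retardance `r` (myelin-density proxy) and direction `φ`; local circular
  variance of doubled angles gives the dispersion/integrity map.
- **Block aggregation** — 0.16 mm² (400 µm × 400 µm) analysis blocks,
  means over tissue pixels, exclusion of blocks with less than 50% tissue,
  ROI/segment majority votes, heatmaps.
- **Statistics** — mean ± SD summaries, Type II covariate-adjusted ANOVA
  with Bonferroni correction (α = 0.05), pairwise segment contrasts, and
  voxel-wise Pearson correlation (α = 0.01), tibble-in/tibble-out with
  `tidy()`/`glance()` methods.

## Worked example

```r
library(wmhpath)

params <- phantom_params(image_size = 32, hist_spacing_um = 50, noise_sd = 4,
                         wmh_gradient_width_um = 1400, nawm_ramp_um = 1000)
cohort <- generate_cohort(n_control = 3, n_hypertension = 3, params, seed = 17)
blocks <- analyze_cohort(cohort, metrics = "LFB", stain_mode = "intensity",
                         seed = 17)
stats  <- cohort_statistics(blocks, metrics = "LFB")
stats$correlations
#> # A tibble: 1 × 7
#>   metric_name      r     n    df statistic p_value significant
#>   <chr>        <dbl> <int> <int>     <dbl>   <dbl> <lgl>
#> 1 LFB         -0.945  2675  2673     -150.       0 TRUE
dplyr::filter(stats$segment_contrasts, comparison == "3 vs 1")
#> # A tibble: 2 × 12
#>   comparison roi   metric_name mean_low_segment mean_high_segment difference
#>   <chr>      <chr> <chr>                  <dbl>             <dbl>      <dbl>
#> 1 3 vs 1     WMH   LFB                     51.0              10.2      -40.8
#> 2 3 vs 1     NAWM  LFB                     73.9              58.4      -15.6
```

The correlation row says that across the 2,675 included 0.16 mm² blocks of
the six synthetic subjects, block-mean FLAIR signal and the LFB myelin
metric are strongly negatively correlated (r = −0.95, p < 0.01) — the
planted inverse FLAIR-pathology gradient, recovered through registration,
deconvolution and aggregation. The contrast rows show the same gradient as
ordered segments: the highest-FLAIR segment (3) carries markedly less
myelin staining than segment 1 in both WMH and NAWM.

Heatmaps of any metric:

```r
tab1 <- process_subject(cohort$subjects$s01, stain_mode = "intensity")
autoplot(render_heatmap(tab1, attr(tab1, "block_grid"), "LFB"))
```

## Vignette

`vignettes/methods.Rmd` documents the phantom's signal model, the network
and training choices, the declared rules where the underlying protocol is
ambiguous (positivity thresholds, dispersion estimator, partial-volume
guard band), and the known limitations of synthetic validation.
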