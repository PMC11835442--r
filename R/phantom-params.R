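#' Parameters of the periventricular white matter phantom
#'
#' Defines the synthetic study conditions: a concentric 2D slice (ventricle
#' hole, periventricular WMH with a radial FLAIR decay ramp, NAWM, GM rim)
#' imaged as a T1/FLAIR pair, with paired stained sections and a PLI stack in
#' a histology frame related to the MRI frame by a known affine, and a planted
#' linear coupling between noiseless FLAIR signal and every pathology field so
#' each pipeline stage has a recoverable ground truth.
#'
#' @param image_size FLAIR pixels per image side (default 48).
#' @param mri_spacing_um FLAIR pixel size in micrometres (default 500, the
#'   post-mortem FLAIR voxel size).
#' @param t1_spacing_um T1 pixel size (default 400).
#' @param hist_spacing_um Histology/PLI pixel size (default 20).
#' @param flair_means Named mean FLAIR signal per tissue
#'   (`background < GM < NAWM < WMH` strictly, the hyperintensity premise).
#' @param t1_means Named mean T1 signal per tissue.
#' @param radii_frac Outer radius of ventricle, WMH, NAWM and GM rings as
#'   fractions of the half image extent.
#' @param wmh_gradient_width_um Width of the FLAIR decay ramp inside the WMH
#'   ring, from the hyperintense core plateau to the WMH/NAWM boundary.
#' @param nawm_ramp_um Distance the ramp extends beyond the WMH boundary into
#'   the NAWM border zone (0 makes NAWM perfectly flat).
#' @param noise_sd Additive Gaussian noise SD on MRI intensities.
#' @param coupling_slope Change in true stain amount (OD units) per unit of
#'   noiseless FLAIR signal; negative plants the inverse FLAIR-pathology
#'   relation.
#' @param coupling_intercept Stain amount at FLAIR signal 0.
#' @param group_effect Named additive shifts (`lfb`, `nfm`, `pli`) applied to
#'   the true pathology fields of the hypertension cohort.
#' @param stain_noise_sdlog SD of multiplicative log-normal noise on stain
#'   amounts.
#' @param counterstain_amount Constant haematoxylin counterstain amount on
#'   tissue in NfM sections.
#' @param pli_retardance_field_params List with `intercept`, `slope`
#'   (retardance per FLAIR unit), `i0` (transmittance), `n_angles`
#'   (rotation steps over 0-180 degrees) and `noise_sd` (additive intensity
#'   noise) for the PLI forward model.
#' @param affine List with `rotation_deg`, `scale`, `shear`,
#'   `translation_um` describing the true MRI-to-histology affine; the
#'   translation is applied on top of a centre-aligning map.
#' @param n_landmarks Number of landmark pairs (>= 10, the manual protocol
#'   minimum).
#' @param landmark_jitter_um SD of Gaussian jitter on histology landmarks.
#' @param radius_jitter_frac Per-subject relative jitter of the ring radii,
#'   giving anatomical variation across a cohort.
#' @param seed Master seed.
#' @return Validated object of class `phantom_params`.
#' @export
phantom_params <- function(
    image_size = 48,
    mri_spacing_um = 500,
    t1_spacing_um = 400,
    hist_spacing_um = 20,
    flair_means = c(background = 20, GM = 80, NAWM = 100, WMH = 160),
    t1_means = c(background = 10, GM = 90, NAWM = 140, WMH = 120),
    radii_frac = c(ventricle = 0.14, wmh = 0.42, nawm = 0.72, gm = 0.92),
    wmh_gradient_width_um = 2000,
    nawm_ramp_um = 1500,
    noise_sd = 4,
    coupling_slope = -0.005,
    coupling_intercept = 1.0,
    group_effect = c(lfb = -0.08, nfm = 0.15, pli = 0),
    stain_noise_sdlog = 0.05,
    counterstain_amount = 0.25,
    pli_retardance_field_params = list(intercept = 0.9, slope = -0.004,
                                       i0 = 200, n_angles = 18, noise_sd = 2),
    affine = list(rotation_deg = 7, scale = c(1.05, 0.95), shear = 0,
                  translation_um = c(300, -200)),
    n_landmarks = 10,
    landmark_jitter_um = 30,
    radius_jitter_frac = 0.02,
    seed = 1) {
  p <- as.list(environment())
  need <- c("background", "GM", "NAWM", "WMH")
  if (!all(need %in% names(p$flair_means)) ||
      any(diff(p$flair_means[need]) <= 0)) {
    abort("flair_means must be strictly ordered background < GM < NAWM < WMH")
  }
  if (any(c(p$mri_spacing_um, p$t1_spacing_um, p$hist_spacing_um) <= 0)) {
    abort("all spacings must be positive")
  }
  if (p$noise_sd < 0 || p$stain_noise_sdlog < 0) abort("noise SDs must be >= 0")
  if (p$n_landmarks < 10) {
    abort("n_landmarks must be >= 10 (the manual landmark protocol minimum)")
  }
  if (is.unsorted(p$radii_frac) || any(p$radii_frac <= 0) ||
      any(p$radii_frac >= 1)) {
    abort("radii_frac must be increasing fractions in (0, 1)")
  }
  prp <- p$pli_retardance_field_params
  if (prp$n_angles < 3) abort("pli n_angles must be >= 3")
  # the concentric layout needs at least ~2 MRI pixels per ring
  half_um <- p$image_size * p$mri_spacing_um / 2
  rings_um <- diff(c(0, p$radii_frac)) * half_um
  if (any(rings_um < 2 * p$mri_spacing_um)) {
    abort(paste("image too small for the concentric ventricle/WMH/NAWM/GM",
                "layout: each ring needs >= 2 MRI pixels"))
  }
  structure(p, class = "phantom_params")
}

#' @export
print.phantom_params <- function(x, ...) {
  cat(sprintf(
    "<phantom_params> %d px FLAIR @ %.0f um, histology @ %.0f um, noise_sd=%.1f, coupling_slope=%.4f\n",
    x$image_size, x$mri_spacing_um, x$hist_spacing_um, x$noise_sd,
    x$coupling_slope))
  invisible(x)
}

# physical extent of the slice in micrometres
phantom_extent_um <- function(params) params$image_size * params$mri_spacing_um

# ring radii in micrometres, optionally with per-subject jitter already applied
phantom_radii_um <- function(params, radii_frac = NULL) {
  rf <- radii_frac %||% params$radii_frac
  rf * phantom_extent_um(params) / 2
}
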