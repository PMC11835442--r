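# --- analytic phantom geometry -------------------------------------------

# Evaluate the noiseless phantom at physical MRI-frame coordinates (um).
# Returns tissue labels (0 bg, 1 GM, 2 NAWM, 3 WMH) and the noiseless FLAIR
# and T1 fields. The FLAIR ramp decays radially from the WMH core plateau
# across the WMH/NAWM boundary into the NAWM border zone.
phantom_eval <- function(params, x_um, y_um, radii_um = NULL) {
  radii <- radii_um %||% phantom_radii_um(params)
  ctr <- phantom_extent_um(params) / 2
  r <- sqrt((x_um - ctr)^2 + (y_um - ctr)^2)
  lab <- integer(length(r))
  lab[r > radii[1] & r <= radii[2]] <- 3L # WMH ring
  lab[r > radii[2] & r <= radii[3]] <- 2L # NAWM ring
  lab[r > radii[3] & r <= radii[4]] <- 1L # GM rim
  fm <- params$flair_means
  flair <- rep(fm[["background"]], length(r))
  flair[lab == 1L] <- fm[["GM"]]
  flair[lab == 2L] <- fm[["NAWM"]]
  flair[lab == 3L] <- fm[["WMH"]]
  ramp_start <- radii[2] - params$wmh_gradient_width_um
  ramp_end <- radii[2] + params$nawm_ramp_um
  in_ramp <- lab %in% c(2L, 3L) & r > ramp_start & r <= ramp_end
  s <- clamp((ramp_end - r[in_ramp]) / (ramp_end - ramp_start), 0, 1)
  flair[in_ramp] <- fm[["NAWM"]] + (fm[["WMH"]] - fm[["NAWM"]]) * s
  tm <- params$t1_means
  t1 <- rep(tm[["background"]], length(r))
  t1[lab == 1L] <- tm[["GM"]]
  t1[lab == 2L] <- tm[["NAWM"]]
  t1[lab == 3L] <- tm[["WMH"]]
  list(labels = lab, flair = flair, t1 = t1, radius = r)
}

# rasterise the analytic phantom on a pixel grid, optionally pulling each
# pixel centre through `to_mri` (histology-frame grids) first
phantom_field <- function(params, grid, radii_um = NULL, to_mri = NULL) {
  grid <- as_grid_spec(grid)
  co <- grid_coords_um(grid)
  x <- co$x; y <- co$y
  if (!is.null(to_mri)) {
    p <- apply_affine(to_mri, cbind(x, y))
    x <- p[, 1]; y <- p[, 2]
  }
  ev <- phantom_eval(params, x, y, radii_um)
  shape <- function(v) matrix(v, grid$dim[1], grid$dim[2])
  list(labels = shape(ev$labels), flair = shape(ev$flair), t1 = shape(ev$t1),
       radius = shape(ev$radius))
}

# per-subject ring radii: relative jitter on the ring fractions
subject_radii <- function(params, seed) {
  if (params$radius_jitter_frac == 0) return(phantom_radii_um(params))
  rf <- with_seed(seed, {
    params$radii_frac * (1 + rnorm(4, 0, params$radius_jitter_frac))
  })
  rf <- sort(clamp(rf, 0.02, 0.98))
  phantom_radii_um(params, rf)
}

# --- generators -----------------------------------------------------------

#' Generate a paired T1/FLAIR slice with truth labels
#'
#' Rasterises the concentric phantom on the native grids of each modality
#' (FLAIR at `mri_spacing_um`, T1 at `t1_spacing_um` over the same physical
#' extent) and adds Gaussian noise. With `noise_sd = 0` every NAWM pixel
#' beyond the border-zone ramp equals `flair_means["NAWM"]` exactly and the
#' truth labels are consistent with the noiseless signal model.
#'
#' @param params A [phantom_params()].
#' @param seed Seed (default `params$seed`).
#' @param radii_um Optional pre-jittered ring radii in micrometres.
#' @return List with `t1`, `flair` ([mri_slice()]), `truth` (label matrix on
#'   the FLAIR grid), `flair_clean` (noiseless FLAIR matrix) and `radii_um`.
#' @export
generate_mri_pair <- function(params, seed = params$seed, radii_um = NULL) {
  radii <- radii_um %||% phantom_radii_um(params)
  extent <- phantom_extent_um(params)
  fg <- grid_spec(rep(params$image_size, 2), params$mri_spacing_um, "mri")
  tg <- grid_spec(rep(round(extent / params$t1_spacing_um), 2),
                  params$t1_spacing_um, "mri")
  ff <- phantom_field(params, fg, radii)
  tf <- phantom_field(params, tg, radii)
  with_seed(derive_seed(seed, "mri"), {
    flair_vals <- ff$flair + rnorm(length(ff$flair), 0, params$noise_sd)
    t1_vals <- tf$t1 + rnorm(length(tf$t1), 0, params$noise_sd)
  })
  list(
    t1 = mri_slice(matrix(t1_vals, tg$dim[1]), params$t1_spacing_um, "T1"),
    flair = mri_slice(matrix(flair_vals, fg$dim[1]), params$mri_spacing_um,
                      "FLAIR"),
    truth = ff$labels,
    flair_clean = ff$flair,
    radii_um = radii
  )
}

# true affine: centre-aligning similarity+shear map plus configured offset
phantom_true_affine <- function(params) {
  a <- params$affine
  base <- make_affine(a$rotation_deg, a$scale, a$shear, c(0, 0))
  ctr <- rep(phantom_extent_um(params) / 2, 2)
  t <- ctr - as.vector(base$A %*% ctr) + a$translation_um
  affine2d(base$A, t, from = "mri", to = "histology")
}

# histology-frame reference grid covering the slice extent
phantom_hist_grid <- function(params) {
  n <- round(phantom_extent_um(params) / params$hist_spacing_um)
  grid_spec(rep(n, 2), params$hist_spacing_um, "histology")
}

#' Generate stained-section images with a planted FLAIR coupling
#'
#' Renders an LFB or NfM section in the histology frame. The true stain
#' amount per tissue pixel is
#' `coupling_intercept + coupling_slope * FLAIR_clean (+ group_effect)`,
#' clipped at zero; multiplicative log-normal noise is applied, and RGB
#' transmission follows the Beer-Lambert forward model
#' (`I_c = 255 * 10^(-amount * stain_vector_c)`), quantised to 8 bits. LFB is
#' a single blue-absorbing stain; NfM is a DAB + haematoxylin mixture with a
#' constant counterstain on tissue. The tissue mask excludes the ventricle
#' hole and everything outside the GM rim.
#'
#' @param params A [phantom_params()].
#' @param stain `"lfb"` or `"nfm"`.
#' @param group `"control"` or `"hypertension"` (applies `group_effect`).
#' @param seed Seed for the stain noise.
#' @param radii_um Optional per-subject ring radii.
#' @param true_affine The MRI-to-histology [affine2d()]; default from
#'   `params`.
#' @return List with `rgb` (8-bit `H x W x 3`), `tissue` (logical matrix),
#'   `truth_amount` (noiseless stain-amount matrix), `stain_matrix` and
#'   `clip_warning` flag.
#' @export
generate_stain_images <- function(params, stain = c("lfb", "nfm"),
                                  group = "control", seed = params$seed,
                                  radii_um = NULL, true_affine = NULL) {
  stain <- match.arg(stain)
  stopifnot(is.finite(params$coupling_slope), is.finite(params$coupling_intercept))
  true_affine <- true_affine %||% phantom_true_affine(params)
  hg <- phantom_hist_grid(params)
  fld <- phantom_field(params, hg, radii_um, to_mri = invert_affine(true_affine))
  tissue <- fld$labels > 0L
  shift <- if (group == "hypertension") params$group_effect[[stain]] else 0
  amount <- params$coupling_intercept + params$coupling_slope * fld$flair + shift
  clipped <- amount < 0 & tissue
  clip_warning <- FALSE
  if (mean(clipped[tissue]) > 0.5) {
    clip_warning <- TRUE
    warn("negative clipping affects >50% of tissue pixels; the planted gradient is no longer identifiable")
  }
  amount <- clamp(amount, 0, Inf)
  amount[!tissue] <- 0
  noisy <- with_seed(derive_seed(seed, "stain", stain), {
    amount * matrix(stats::rlnorm(length(amount), 0, params$stain_noise_sdlog),
                    nrow(amount))
  })
  if (stain == "lfb") {
    M <- stain_matrix(list(lfb = stain_vector("lfb")))
    amounts <- array(noisy, c(dim(noisy), 1))
  } else {
    M <- stain_matrix(list(dab = stain_vector("dab"),
                           hematoxylin = stain_vector("hematoxylin")))
    counter <- matrix(0, nrow(noisy), ncol(noisy))
    counter[tissue] <- params$counterstain_amount
    amounts <- array(c(noisy, counter), c(dim(noisy), 2))
  }
  rgb <- stains_to_rgb(amounts, M, quantize = TRUE)
  list(rgb = rgb, tissue = tissue, truth_amount = amount,
       stain_matrix = M, clip_warning = clip_warning)
}

#' Generate the true PLI direction and retardance fields
#'
#' Retardance (the myelin-density analog) is coupled linearly to the
#' noiseless FLAIR field and clipped into `[0, 1]`; the fiber direction field
#' is tangential around the ventricle (periventricular fibers wrap the
#' horn). Non-tissue pixels get retardance 0.
#'
#' @inheritParams generate_stain_images
#' @return List with `direction_deg`, `retardance`, `tissue` matrices on the
#'   histology grid.
#' @export
generate_pli_fields <- function(params, group = "control", radii_um = NULL,
                                true_affine = NULL) {
  prp <- params$pli_retardance_field_params
  true_affine <- true_affine %||% phantom_true_affine(params)
  hg <- phantom_hist_grid(params)
  inv <- invert_affine(true_affine)
  fld <- phantom_field(params, hg, radii_um, to_mri = inv)
  tissue <- fld$labels > 0L
  shift <- if (group == "hypertension") params$group_effect[["pli"]] else 0
  r <- clamp(prp$intercept + prp$slope * fld$flair + shift, 0, 1)
  r[!tissue] <- 0
  co <- grid_coords_um(hg)
  p <- apply_affine(inv, cbind(co$x, co$y))
  ctr <- phantom_extent_um(params) / 2
  phi <- (atan2(p[, 2] - ctr, p[, 1] - ctr) * 180 / pi + 90) %% 180
  list(direction_deg = matrix(phi, hg$dim[1]), retardance = r, tissue = tissue)
}

#' Generate a PLI rotation stack from truth fields
#'
#' Forward model per pixel and rotation angle:
#' `I(rho) = (I0/2) * (1 + r * sin(2 rho - 2 phi)) + N(0, noise_sd)`.
#'
#' @param direction_deg Matrix of true fiber directions (degrees).
#' @param retardance Matrix of true retardance values in `[0, 1]`.
#' @param angles_deg Equally spaced rotation angles over `[0, 180)`.
#' @param i0 Transmittance.
#' @param noise_sd Additive Gaussian intensity noise.
#' @param spacing_um Pixel size of the stack.
#' @param seed Seed for the noise.
#' @return A [pli_stack()].
#' @export
generate_pli_stack <- function(direction_deg, retardance, angles_deg,
                               i0 = 200, noise_sd = 0, spacing_um = 20,
                               seed = 1) {
  if (any(retardance < 0 | retardance > 1, na.rm = TRUE)) {
    abort("retardance must lie in [0, 1]")
  }
  rho <- angles_deg * pi / 180
  phi <- direction_deg * pi / 180
  d <- dim(retardance)
  imgs <- array(0, c(d[1], d[2], length(rho)))
  for (k in seq_along(rho)) {
    imgs[, , k] <- (i0 / 2) * (1 + retardance * sin(2 * rho[k] - 2 * phi))
  }
  if (noise_sd > 0) {
    imgs <- imgs + with_seed(derive_seed(seed, "pli"), {
      array(rnorm(length(imgs), 0, noise_sd), dim(imgs))
    })
  }
  pli_stack(imgs, angles_deg, spacing_um)
}

#' Generate paired landmark sets
#'
#' Samples `n` points in the central part of the slice, rejects (and
#' resamples) collinear configurations, and maps them through the true
#' affine plus Gaussian jitter of the stated SD to obtain the histology-frame
#' set.
#'
#' @param true_affine The MRI-to-histology [affine2d()].
#' @param n Number of landmarks (>= 3; the manual protocol uses >= 10, and
#'   fewer trigger a warning downstream).
#' @param jitter_um SD of the jitter on histology coordinates.
#' @param seed Seed.
#' @param extent_um Physical side length of the slice.
#' @return List with `mri` and `hist` [landmark_set()]s.
#' @export
generate_landmarks <- function(true_affine, n = 10, jitter_um = 0, seed = 1,
                               extent_um = 24000) {
  if (n < 3) abort("need at least 3 landmarks")
  with_seed(derive_seed(seed, "landmarks"), {
    for (try in 1:20) {
      x <- runif(n, 0.1, 0.9) * extent_um
      y <- runif(n, 0.1, 0.9) * extent_um
      if (!points_collinear(cbind(x, y))) break
      if (try == 20) abort("failed to sample non-collinear landmarks")
    }
    mri <- landmark_set(x, y, frame = "mri")
    h <- apply_affine(true_affine, mri)
    if (jitter_um > 0) {
      h$x_um <- h$x_um + rnorm(n, 0, jitter_um)
      h$y_um <- h$y_um + rnorm(n, 0, jitter_um)
    }
    list(mri = mri, hist = h)
  })
}

#' Generate one complete synthetic subject
#'
#' Bundles the MRI pair, truth labels, stained sections, PLI truth fields and
#' stack, true affine and landmark pairs for one subject, with per-subject
#' anatomical variation drawn from the subject seed.
#'
#' @param params A [phantom_params()].
#' @param group `"control"` or `"hypertension"`.
#' @param subject_id Subject identifier string.
#' @param seed Subject seed (default derived from `params$seed` and the id).
#' @return Object of class `wmh_subject`.
#' @export
generate_subject <- function(params, group = "control",
                             subject_id = "s01",
                             seed = derive_seed(params$seed, subject_id)) {
  radii <- subject_radii(params, derive_seed(seed, "radii"))
  mri <- generate_mri_pair(params, seed = seed, radii_um = radii)
  ta <- phantom_true_affine(params)
  lfb <- generate_stain_images(params, "lfb", group, seed, radii, ta)
  nfm <- generate_stain_images(params, "nfm", group, seed, radii, ta)
  pli <- generate_pli_fields(params, group, radii, ta)
  prp <- params$pli_retardance_field_params
  angles <- seq(0, 180 - 180 / prp$n_angles, length.out = prp$n_angles)
  stack <- generate_pli_stack(pli$direction_deg, pli$retardance, angles,
                              i0 = prp$i0, noise_sd = prp$noise_sd,
                              spacing_um = params$hist_spacing_um, seed = seed)
  lms <- generate_landmarks(ta, params$n_landmarks, params$landmark_jitter_um,
                            seed, phantom_extent_um(params))
  structure(
    list(subject_id = subject_id, group = group, seed = seed,
         t1 = mri$t1, flair = mri$flair, truth_labels = mri$truth,
         flair_clean = mri$flair_clean, radii_um = radii,
         lfb = lfb, nfm = nfm,
         pli_fields = pli, pli_stack = stack,
         true_affine = ta,
         landmarks_mri = lms$mri, landmarks_hist = lms$hist),
    class = "wmh_subject"
  )
}

#' @export
print.wmh_subject <- function(x, ...) {
  cat(sprintf("<wmh_subject> %s (%s), FLAIR %d px, histology %d px\n",
              x$subject_id, x$group, nrow(x$flair$values),
              nrow(x$lfb$tissue)))
  invisible(x)
}

#' Generate a two-group synthetic cohort
#'
#' Builds `n_control + n_hypertension` subjects with seeds derived
#' deterministically from the master seed and returns them with a manifest.
#' When `dir` is given every subject is also written to disk (NIfTI MRI,
#' TIFF stains and PLI stack, TSV landmarks and angles, YAML parameter echo)
#' and the manifest, including file paths, is saved as `manifest.csv`.
#'
#' @param n_control,n_hypertension Group sizes (>= 1).
#' @param params A [phantom_params()].
#' @param seed Master seed (default `params$seed`).
#' @param dir Optional output directory.
#' @return Object of class `wmh_cohort`: list with `subjects`, `manifest`
#'   (tibble) and `params`.
#' @export
generate_cohort <- function(n_control, n_hypertension, params,
                            seed = params$seed, dir = NULL) {
  stopifnot(n_control >= 1, n_hypertension >= 1)
  groups <- c(rep("control", n_control), rep("hypertension", n_hypertension))
  ids <- sprintf("s%02d", seq_along(groups))
  subjects <- purrr::map2(ids, groups, function(id, g) {
    generate_subject(params, group = g, subject_id = id,
                     seed = derive_seed(seed, id, g))
  })
  names(subjects) <- ids
  manifest <- tibble::tibble(
    subject = ids, group = groups,
    seed = vapply(subjects, function(s) s$seed, numeric(1)),
    coupling_slope = params$coupling_slope,
    coupling_intercept = params$coupling_intercept
  )
  if (!is.null(dir)) {
    manifest$path <- vapply(subjects, function(s) {
      write_subject(s, file.path(dir, s$subject_id), params)
    }, character(1))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    yaml::write_yaml(params_to_list(params), file.path(dir, "params.yaml"))
  }
  structure(list(subjects = subjects, manifest = manifest, params = params),
            class = "wmh_cohort")
}
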