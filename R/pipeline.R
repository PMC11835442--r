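#' Run the full MRI-histopathology pipeline on one subject
#'
#' Registration, grading, quantification and aggregation on the histology
#' reference grid:
#' landmark-based affine estimation; warping of the FLAIR slice (bilinear)
#' and the tissue labels (nearest-neighbour) onto the reference section;
#' k-means grading of WMH and NAWM into intensity segments; colour
#' deconvolution of the LFB and NfM sections with control-region thresholds
#' (positive control: NAWM; background: non-tissue); PLI retardance and
#' dispersion maps; and aggregation into 0.16 mm^2 blocks joined with the
#' block-mean FLAIR signal.
#'
#' @param subject A `wmh_subject` from [generate_subject()].
#' @param labels Label source: `"truth"` (the generator's truth map) or a
#'   trained `unet_ensemble` used to segment the MRI pair.
#' @param block_side_um Analysis block side (default 400, i.e. 0.16 mm^2).
#' @param stain_mode [stain_metric()] mode, `"area"` or `"intensity"`.
#' @param metrics Character subset of
#'   `c("LFB", "NfM", "PLI_myelin_density", "PLI_integrity")`.
#' @param k Number of intensity segments per ROI.
#' @param seed Seed for the k-means restarts.
#' @param min_tissue Block inclusion threshold (default 0.5).
#' @param pv_guard_um Width of the partial-volume guard band: white matter
#'   pixels within this distance of a CSF/background or GM boundary are
#'   excluded from the registered FLAIR signal, the intensity grading and the
#'   ROI votes, because bilinear resampling of the coarse MRI mixes non-WM
#'   signal into them (the classic CSF partial-volume artefact at the
#'   ventricle wall). Defaults to one FLAIR voxel; 0 disables.
#' @return An `analysis_table` tibble (one row per included block and
#'   metric), with the estimated transform and landmark RMSE in attributes
#'   `transform` and `registration_rmse_um`.
#' @export
process_subject <- function(subject, labels = "truth", block_side_um = 400,
                            stain_mode = c("area", "intensity"),
                            metrics = c("LFB", "NfM", "PLI_myelin_density",
                                        "PLI_integrity"),
                            k = 3, seed = 1, min_tissue = 0.5,
                            pv_guard_um = NULL) {
  stain_mode <- match.arg(stain_mode)
  est <- estimate_affine(subject$landmarks_mri, subject$landmarks_hist)
  rmse <- registration_rmse(est, subject$landmarks_mri, subject$landmarks_hist)
  hd <- dim(subject$lfb$tissue)
  hg <- grid_spec(hd, subject$pli_stack$spacing_um, "histology")
  tissue <- subject$lfb$tissue

  flair_reg <- warp_to_reference(subject$flair, est, hg, "bilinear")
  lab_mri <- if (inherits(labels, "unet_ensemble")) {
    probabilities_to_labels(predict_ensemble(labels, subject_to_training(subject)$x))
  } else if (identical(labels, "truth")) {
    subject$truth_labels
  } else {
    abort("`labels` must be \"truth\" or a unet_ensemble")
  }
  seg_reg <- warp_to_reference(lab_mri, est, hg, "nearest",
                               img_spacing_um = subject$flair$spacing_um)

  pv_guard_um <- pv_guard_um %||% subject$flair$spacing_um[1]
  if (pv_guard_um > 0) {
    guard_px <- ceiling(pv_guard_um / hg$spacing_um[1])
    non_wm <- is.na(seg_reg) | seg_reg < 2
    near_non_wm <- box_sum(non_wm * 1, 2 * guard_px + 1) > 0
    guarded <- near_non_wm & !non_wm
    flair_reg[guarded] <- NA_real_
    seg_reg[guarded] <- NA_integer_
  }

  graded <- grade_rois(flair_reg, seg_reg, k = k,
                       seed = derive_seed(seed, subject$subject_id))

  metric_imgs <- list()
  bg_region <- !tissue
  nawm_region <- tissue & !is.na(seg_reg) & seg_reg == 2
  if ("LFB" %in% metrics) {
    M <- stain_matrix(list(lfb = stain_vector("lfb")))
    ch <- stain_channel(deconvolve(rgb_to_od(subject$lfb$rgb), M), "lfb")
    thr <- determine_threshold(ch, nawm_region, bg_region)
    metric_imgs$LFB <- stain_metric(ch, thr, tissue, stain_mode)
  }
  if ("NfM" %in% metrics) {
    M <- stain_matrix(list(dab = stain_vector("dab"),
                           hematoxylin = stain_vector("hematoxylin")))
    ch <- stain_channel(deconvolve(rgb_to_od(subject$nfm$rgb), M), "dab")
    thr <- determine_threshold(ch, nawm_region, bg_region)
    metric_imgs$NfM <- stain_metric(ch, thr, tissue, stain_mode)
  }
  if (any(c("PLI_myelin_density", "PLI_integrity") %in% metrics)) {
    fit <- fit_pli(subject$pli_stack)
    if ("PLI_myelin_density" %in% metrics) {
      m <- fit$retardance * 100
      m[!fit$valid | !tissue] <- NA_real_
      metric_imgs$PLI_myelin_density <- m
    }
    if ("PLI_integrity" %in% metrics) {
      di <- dispersion_map(fit$direction_deg, window = 5,
                           valid = fit$valid & tissue)
      metric_imgs$PLI_integrity <- di
    }
  }

  grid <- make_block_grid(hd, subject$pli_stack$spacing_um, block_side_um)
  out <- join_blocks(flair_reg, seg_reg, graded, metric_imgs, tissue, grid,
                     subject = subject$subject_id, group = subject$group,
                     min_tissue = min_tissue)
  attr(out, "transform") <- est
  attr(out, "registration_rmse_um") <- rmse
  attr(out, "block_grid") <- grid
  out
}

#' Run the pipeline over a cohort
#'
#' Applies [process_subject()] to every subject and binds the block tables.
#'
#' @param cohort A `wmh_cohort` from [generate_cohort()].
#' @param ... Passed to [process_subject()].
#' @return Combined `analysis_table`.
#' @export
analyze_cohort <- function(cohort, ...) {
  tabs <- purrr::map(cohort$subjects, process_subject, ...)
  out <- dplyr::bind_rows(tabs)
  class(out) <- c("analysis_table", class(out))
  out
}

#' Cohort-level statistical battery
#'
#' The full reporting set on an analysis table: group/ROI/segment summaries,
#' a covariate-free two-way (group x ROI) Type II ANOVA per metric, pairwise
#' segment contrasts with Bonferroni correction within each ROI, and the
#' pooled voxel-wise Pearson correlation between block FLAIR signal and each
#' metric (significance at `alpha = 0.01`).
#'
#' @param table An `analysis_table`.
#' @param metrics Metrics to analyse (default: all present).
#' @param covariates Optional covariate column names for the ANOVA.
#' @return List of tibbles: `summary`, `anova`, `segment_contrasts`,
#'   `correlations`.
#' @export
cohort_statistics <- function(table, metrics = unique(table$metric_name),
                              covariates = character()) {
  tb <- dplyr::filter(table, .data$included)
  anovas <- purrr::map(metrics, function(m) {
    d <- dplyr::filter(tb, .data$metric_name == m)
    factors <- c(if (length(unique(d$group)) > 1) "group", "roi")
    fit <- anova_glm(d, "metric_value", factors, covariates)
    dplyr::mutate(tidy(fit), metric_name = m, .before = 1)
  })
  contrasts <- purrr::map(metrics, function(m) {
    dplyr::bind_rows(
      pairwise_segments(tb, m, "WMH"),
      pairwise_segments(tb, m, "NAWM")
    )
  })
  cors <- purrr::map(metrics, function(m) {
    d <- dplyr::filter(tb, .data$metric_name == m)
    dplyr::mutate(pearson(d$flair_mean, d$metric_value), metric_name = m,
                  .before = 1)
  })
  list(
    summary = summarize_blocks(tb),
    anova = dplyr::bind_rows(anovas),
    segment_contrasts = dplyr::bind_rows(contrasts),
    correlations = dplyr::bind_rows(cors)
  )
}
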