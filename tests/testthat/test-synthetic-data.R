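test_that("noiseless phantom matches the analytic signal model", {
  p <- phantom_clean_params(nawm_ramp_um = 0)
  mp <- generate_mri_pair(p)
  expect_setequal(unique(as.vector(mp$truth)), 0:3)
  # flat NAWM: with no border-zone ramp every NAWM pixel is exactly the mean
  expect_true(all(mp$flair$values[mp$truth == 2] == 100))
  # hyperintensity premise: every WMH pixel >= every NAWM pixel (noiseless)
  expect_true(min(mp$flair$values[mp$truth == 3]) >=
                max(mp$flair$values[mp$truth == 2]))
  # the ramp is monotone: FLAIR never increases with radius inside WM
  fld <- wmhpath:::phantom_field(p, grid_spec(c(64, 64), 250, "mri"))
  wm <- fld$labels >= 2
  ord <- order(fld$radius[wm])
  expect_true(all(diff(fld$flair[wm][ord]) <= 1e-9))
})

test_that("generators are pure functions of (params, seed)", {
  p <- phantom_test_params()
  s1 <- generate_subject(p, "hypertension", "sX", seed = 42)
  s2 <- generate_subject(p, "hypertension", "sX", seed = 42)
  expect_identical(s1$flair$values, s2$flair$values)
  expect_identical(s1$lfb$rgb, s2$lfb$rgb)
  expect_identical(s1$pli_stack$images, s2$pli_stack$images)
  expect_identical(s1$landmarks_hist, s2$landmarks_hist)
  c1 <- generate_cohort(2, 2, p, seed = 5)
  c2 <- generate_cohort(2, 2, p, seed = 5)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$subjects$s03$nfm$rgb, c2$subjects$s03$nfm$rgb)
})

test_that("MRI noise model has the stated mean and scale", {
  p <- phantom_params(image_size = 64, noise_sd = 5, nawm_ramp_um = 0,
                      radius_jitter_frac = 0)
  mp <- generate_mri_pair(p, seed = 11)
  vals <- mp$flair$values[mp$truth == 2]
  n <- length(vals)
  expect_gt(n, 800)
  # Monte-Carlo check: sample mean within 3 standard errors of the truth
  expect_lt(abs(mean(vals) - 100), 3 * 5 / sqrt(n))
})

test_that("stain forward model obeys Beer-Lambert limits", {
  # zero absorbance -> pure white transmission
  p0 <- phantom_clean_params(coupling_slope = 0, coupling_intercept = 0,
                             counterstain_amount = 0)
  st <- generate_stain_images(p0, "lfb")
  expect_true(all(st$rgb[st$tissue] == 255))
  expect_true(all(st$truth_amount == 0))
  # null coupling -> constant truth field, no pixel-level correlation left
  p1 <- phantom_test_params(coupling_slope = 0)
  s <- generate_subject(p1, "control", "s0")
  expect_equal(length(unique(s$lfb$truth_amount[s$lfb$tissue])), 1)
  M <- stain_matrix(list(lfb = stain_vector("lfb")))
  ch <- stain_channel(deconvolve(rgb_to_od(s$lfb$rgb), M), "lfb")
  hg <- wmhpath:::phantom_hist_grid(p1)
  fld <- wmhpath:::phantom_field(p1, hg, s$radii_um,
                                 to_mri = invert_affine(s$true_affine))
  expect_lt(abs(cor(fld$flair[s$lfb$tissue], ch[s$lfb$tissue])), 0.05)
})

test_that("planted stain slope is recovered by regression on pixels", {
  p <- phantom_test_params()
  s <- generate_subject(p, "control", "s1")
  M <- stain_matrix(list(lfb = stain_vector("lfb")))
  ch <- stain_channel(deconvolve(rgb_to_od(s$lfb$rgb), M), "lfb")
  hg <- wmhpath:::phantom_hist_grid(p)
  fld <- wmhpath:::phantom_field(p, hg, s$radii_um,
                                 to_mri = invert_affine(s$true_affine))
  t <- s$lfb$tissue & fld$labels >= 2 # white matter, no clipping there
  fit <- stats::lm(ch[t] ~ fld$flair[t])
  expect_lt(abs(stats::coef(fit)[2] - p$coupling_slope),
            0.05 * abs(p$coupling_slope))
})

test_that("excess negative clipping triggers the identifiability warning", {
  p <- phantom_clean_params(coupling_intercept = -1)
  expect_warning(generate_stain_images(p, "lfb"), "clipping")
})

test_that("landmark pairs follow the true affine plus stated jitter", {
  ta <- make_affine(0, c(1, 1), 0, c(300, -200))
  lm0 <- generate_landmarks(ta, n = 10, jitter_um = 0, seed = 3,
                            extent_um = 16000)
  expect_equal(lm0$hist$x_um, lm0$mri$x_um + 300)
  expect_equal(lm0$hist$y_um, lm0$mri$y_um - 200)
  ident <- affine2d(diag(2), c(0, 0))
  lmi <- generate_landmarks(ident, n = 12, jitter_um = 0, seed = 3,
                            extent_um = 16000)
  expect_equal(cbind(lmi$hist$x_um, lmi$hist$y_um),
               cbind(lmi$mri$x_um, lmi$mri$y_um))
  # residual RMSE of the refit stays on the jitter scale
  ta2 <- make_affine(10, c(1.1, 0.9), 0.05, c(500, 250))
  rmses <- vapply(1:10, function(sd) {
    lm <- generate_landmarks(ta2, n = 10, jitter_um = 50, seed = sd,
                             extent_um = 16000)
    est <- suppressWarnings(estimate_affine(lm$mri, lm$hist))
    registration_rmse(est, lm$mri, lm$hist)
  }, numeric(1))
  expect_true(all(rmses > 20 & rmses < 90))
})

test_that("PLI stack generation matches the sinusoid closed form", {
  angles <- seq(0, 170, 10)
  st <- generate_pli_stack(matrix(0, 1, 1), matrix(1, 1, 1), angles,
                           i0 = 200, noise_sd = 0, spacing_um = 20)
  expect_equal(as.vector(st$images),
               100 * (1 + sin(2 * angles * pi / 180)), tolerance = 1e-12)
  # zero retardance -> identical intensity at all angles
  st0 <- generate_pli_stack(matrix(37, 2, 2), matrix(0, 2, 2), angles,
                            i0 = 120, noise_sd = 0, spacing_um = 20)
  expect_true(all(st0$images == 60))
  expect_error(
    generate_pli_stack(matrix(0, 1, 1), matrix(1.2, 1, 1), angles),
    "retardance")
})

test_that("a hypertension group effect is detectable with matching sign", {
  p <- phantom_test_params(group_effect = c(lfb = -0.2, nfm = 0.15, pli = 0),
                           noise_sd = 2, stain_noise_sdlog = 0.03)
  coh <- generate_cohort(2, 2, p, seed = 21)
  tab <- analyze_cohort(coh, metrics = "LFB", stain_mode = "intensity")
  fit <- anova_glm(dplyr::filter(tab, included), "metric_value",
                   c("group", "roi"))
  row <- dplyr::filter(tidy(fit), effect == "group")
  expect_lt(row$p_bonferroni, 0.05)
  m <- dplyr::filter(summarize_blocks(tab), segment == "all",
                     roi == "NAWM")
  expect_lt(m$mean[m$group == "hypertension"], m$mean[m$group == "control"])
})

test_that("images too small for the concentric layout are rejected", {
  expect_error(phantom_params(image_size = 8), "too small")
  expect_error(phantom_params(flair_means = c(background = 20, GM = 120,
                                              NAWM = 100, WMH = 160)),
               "ordered")
  expect_error(phantom_params(n_landmarks = 5), "landmark")
})
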