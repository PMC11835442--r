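# Shared fixtures: a reduced-size phantom keeps the suite fast while
# preserving every structural feature (concentric rings, border-zone ramp,
# affine frame offset, all noise sources).

phantom_test_params <- function(...) {
  defaults <- list(image_size = 32, hist_spacing_um = 50, noise_sd = 4,
                   wmh_gradient_width_um = 1400, nawm_ramp_um = 1000)
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

# noiseless variant: every planted field is exactly recoverable
phantom_clean_params <- function(...) {
  defaults <- list(noise_sd = 0, stain_noise_sdlog = 0,
                   landmark_jitter_um = 0, radius_jitter_frac = 0,
                   pli_retardance_field_params = list(
                     intercept = 0.9, slope = -0.004, i0 = 200,
                     n_angles = 18, noise_sd = 0))
  do.call(phantom_test_params, utils::modifyList(defaults, list(...)))
}

.fixture_env <- new.env(parent = emptyenv())

fixture_subject <- function() {
  if (is.null(.fixture_env$subject)) {
    .fixture_env$subject <- generate_subject(phantom_test_params(),
                                             "control", "s01")
  }
  .fixture_env$subject
}

fixture_table <- function() {
  if (is.null(.fixture_env$table)) {
    .fixture_env$table <- process_subject(fixture_subject(),
                                          stain_mode = "intensity", seed = 1)
  }
  .fixture_env$table
}

# independent least-squares oracle for the affine fit: explicit normal
# equations, solved per output coordinate
affine_normal_equations <- function(src, dst) {
  X <- cbind(src, 1)
  XtX <- t(X) %*% X
  sol <- solve(XtX, t(X) %*% dst)
  list(A = t(sol[1:2, , drop = FALSE]), t = as.numeric(sol[3, ]))
}
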