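#' Polarized light imaging rotation stack
#'
#' `N` transmitted-light intensity images acquired at equally spaced
#' polarizer rotation angles covering `[0, 180)` degrees. Each pixel follows
#' the PLI sinusoid `I(rho) = (I0/2) * (1 + r * sin(2 rho - 2 phi))`, with
#' transmittance `I0`, retardance `r = |sin delta|` (the myelin-density
#' proxy) and in-plane fiber direction `phi`.
#'
#' @param images `H x W x N` numeric array of intensities.
#' @param angles_deg Rotation angles in degrees, strictly increasing, equal
#'   steps, within `[0, 180)`.
#' @param spacing_um Physical pixel size in micrometres.
#' @return An object of class `pli_stack`.
#' @export
pli_stack <- function(images, angles_deg, spacing_um) {
  d <- dim(images)
  if (length(d) != 3) abort("`images` must be an H x W x N array")
  n <- length(angles_deg)
  if (d[3] != n) abort("number of images and angles differ")
  if (n < 3) abort("at least 3 rotation angles are required")
  steps <- diff(angles_deg)
  if (any(steps <= 0) || max(steps) - min(steps) > 1e-9) {
    abort("angles must be strictly increasing with equal steps")
  }
  if (min(angles_deg) < 0 || max(angles_deg) >= 180) {
    abort("angles must lie in [0, 180) degrees")
  }
  structure(list(images = images, angles_deg = as.numeric(angles_deg),
                 spacing_um = as.numeric(spacing_um)),
            class = "pli_stack")
}

#' Fit the PLI sinusoid at every pixel
#'
#' Discrete Fourier estimation on the equally spaced rotation series:
#' `a0 = mean(I)`, `a2 = (2/N) sum I cos(2 rho)`, `b2 = (2/N) sum I sin(2 rho)`;
#' then `I0 = 2 a0`, `r = sqrt(a2^2 + b2^2) / a0` and
#' `phi = atan2(-a2, b2) / 2` wrapped into `[0, 180)` degrees. For equally
#' spaced angles this equals the least-squares sinusoid fit. Pixels with
#' `a0 <= 0` are flagged invalid; a constant series gives `r = 0` with
#' `phi` reported as 0.
#'
#' @param stack A [pli_stack()].
#' @return List of matrices `transmittance` (`I0`), `direction_deg` (`phi`),
#'   `retardance` (`r`, clipped into `[0, 1]`) and logical `valid`.
#' @export
fit_pli <- function(stack) {
  d <- dim(stack$images)
  n <- d[3]
  flat <- matrix(stack$images, d[1] * d[2], n)
  rho <- stack$angles_deg * pi / 180
  a0 <- rowMeans(flat)
  a2 <- (2 / n) * as.vector(flat %*% cos(2 * rho))
  b2 <- (2 / n) * as.vector(flat %*% sin(2 * rho))
  valid <- a0 > 0
  r <- rep(NA_real_, length(a0))
  phi <- rep(NA_real_, length(a0))
  r[valid] <- sqrt(a2[valid]^2 + b2[valid]^2) / a0[valid]
  phi[valid] <- (atan2(-a2[valid], b2[valid]) / 2) * 180 / pi
  phi[valid] <- phi[valid] %% 180
  phi[valid & r < 1e-12] <- 0
  r <- clamp(r, 0, 1)
  list(
    transmittance = matrix(2 * a0, d[1], d[2]),
    direction_deg = matrix(phi, d[1], d[2]),
    retardance = matrix(r, d[1], d[2]),
    valid = matrix(valid, d[1], d[2])
  )
}

#' Fit a single PLI pixel series
#'
#' @param series Intensity values at each rotation angle.
#' @param angles_deg The rotation angles (degrees, equal steps).
#' @return List with `I0`, `phi_deg`, `r` and `valid`.
#' @export
fit_pli_pixel <- function(series, angles_deg) {
  st <- pli_stack(array(series, c(1, 1, length(series))), angles_deg, 1)
  f <- fit_pli(st)
  list(I0 = f$transmittance[1, 1], phi_deg = f$direction_deg[1, 1],
       r = f$retardance[1, 1], valid = f$valid[1, 1])
}

#' Retardance map and summary
#'
#' Per-pixel retardance from [fit_pli()], reported on a 0-100 percent scale
#' as the myelin-density proxy; invalid (opaque) pixels are excluded from the
#' mean.
#'
#' @param stack A [pli_stack()].
#' @return List with `map_pct` (matrix, `NA` where invalid) and `mean_pct`.
#' @export
retardance_map <- function(stack) {
  f <- fit_pli(stack)
  m <- f$retardance * 100
  m[!f$valid] <- NA_real_
  if (!any(f$valid)) abort("all pixels are invalid (non-positive transmittance)")
  list(map_pct = m, mean_pct = mean(m[f$valid]))
}

#' Fiber-dispersion / microstructural-integrity map
#'
#' Local circular variance of the axial fiber directions: within an odd
#' square window the directions are doubled (axial data have period 180
#' degrees), averaged as unit vectors, and the variance
#' `V = 1 - ||mean unit vector||` is converted to an integrity percentage
#' `100 * (1 - V)`. A perfectly coherent window scores 100; orientations
#' spread uniformly (or two orthogonal populations in equal parts) score 0.
#' This local estimator is the package's declared stand-in for the dispersion
#' measure of dedicated PLI pipelines and is labelled as such in outputs.
#'
#' @param direction_deg Matrix of fiber directions in degrees.
#' @param window Odd window side length in pixels (default 5).
#' @param valid Logical matrix of pixels to use (default: all finite).
#' @return Matrix of integrity percentages in `[0, 100]`; `NA` where the
#'   window holds no valid pixel.
#' @export
dispersion_map <- function(direction_deg, window = 5, valid = NULL) {
  if (window %% 2 != 1 || window < 3) abort("window must be odd and >= 3")
  if (window > nrow(direction_deg) || window > ncol(direction_deg)) {
    abort("window larger than image")
  }
  valid <- valid %||% is.finite(direction_deg)
  a2 <- 2 * direction_deg * pi / 180
  C <- ifelse(valid, cos(a2), 0)
  S <- ifelse(valid, sin(a2), 0)
  n <- box_sum(valid * 1, window)
  R <- sqrt(box_sum(C, window)^2 + box_sum(S, window)^2)
  out <- ifelse(n > 0, 100 * R / n, NA_real_)
  out[!valid] <- NA_real_
  clamp(out, 0, 100)
}
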