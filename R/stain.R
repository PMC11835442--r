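#' Built-in stain optical-density vectors
#'
#' Package-default unit-length optical-density (OD) vectors for the stains
#' used in periventricular white matter sections: haematoxylin and DAB
#' (standard colour-deconvolution values) and a single blue-absorbing vector
#' for Luxol Fast Blue. All vectors are configuration constants and can be
#' overridden wherever a [stain_matrix()] is accepted.
#'
#' @param name One of `"hematoxylin"`, `"dab"`, `"lfb"`.
#' @return A unit-length numeric RGB absorbance vector.
#' @export
stain_vector <- function(name = c("hematoxylin", "dab", "lfb")) {
  name <- match.arg(name)
  v <- switch(name,
    hematoxylin = c(0.650, 0.704, 0.286),
    dab         = c(0.268, 0.570, 0.776),
    # LFB transmits blue, absorbs red/green
    lfb         = c(0.740, 0.630, 0.230)
  )
  v / sqrt(sum(v^2))
}

#' Stain matrix for colour deconvolution
#'
#' Collects up to three unit-length stain OD vectors into the mixing matrix of
#' the Beer-Lambert model. With fewer than three stains the matrix is padded
#' with unit residual vectors orthogonal to the given stains so it is always
#' invertible; padded channels are named `"residual*"`.
#'
#' @param vectors Named list of RGB absorbance vectors (rows of the matrix).
#' @return A matrix of class `stain_matrix`, one unit row per channel.
#' @export
stain_matrix <- function(vectors) {
  if (is.matrix(vectors)) {
    vectors <- split(vectors, seq_len(nrow(vectors)))
  }
  nm <- names(vectors) %||% paste0("stain", seq_along(vectors))
  M <- do.call(rbind, lapply(vectors, function(v) v / sqrt(sum(v^2))))
  if (nrow(M) > 3) abort("at most 3 stain vectors are supported")
  if (qr(M)$rank < nrow(M)) abort("stain vectors are linearly dependent")
  n_given <- nrow(M)
  while (nrow(M) < 3) {
    # unit vector orthogonal to the rows so far
    ns <- svd(M, nu = 0, nv = 3)$v[, (nrow(M) + 1):3, drop = FALSE]
    M <- rbind(M, ns[, 1])
    nm <- c(nm, paste0("residual", nrow(M) - n_given))
  }
  dimnames(M) <- list(nm, c("R", "G", "B"))
  structure(M, class = c("stain_matrix", "matrix"), n_stains = n_given)
}

#' Convert an RGB image to optical density
#'
#' Per-channel Beer-Lambert transform `OD = -log10((I + eps) / 255)` for
#' 8-bit intensities. `eps = 1` keeps saturated black pixels finite; set
#' `eps = 0` for float (unquantised) transmission images.
#'
#' @param rgb Numeric array `H x W x 3` (or `N x 3` matrix) of intensities on
#'   the 0-255 scale.
#' @param eps Offset added to the intensity before the log; default 1.
#' @return Array/matrix of optical densities, same shape as the input.
#' @export
rgb_to_od <- function(rgb, eps = 1) {
  d <- dim(rgb)
  if (is.null(d) || !(length(d) %in% c(2, 3)) || d[length(d)] != 3) {
    abort("`rgb` must be an H x W x 3 array or N x 3 matrix")
  }
  -log10((rgb + eps) / 255)
}

#' Beer-Lambert forward model
#'
#' Renders per-pixel stain amounts into 8-bit-scale RGB transmission:
#' `I_c = 255 * 10^(-sum_s amount_s * M[s, c])`.
#'
#' @param amounts `H x W x S` array (or `N x S` matrix) of stain amounts in
#'   OD units.
#' @param M A [stain_matrix()] whose first `S` rows are used.
#' @param quantize Round to integer 8-bit levels (default `FALSE`).
#' @return RGB array/matrix on the 0-255 scale.
#' @export
stains_to_rgb <- function(amounts, M, quantize = FALSE) {
  d <- dim(amounts)
  flat <- if (length(d) == 3) matrix(amounts, d[1] * d[2], d[3]) else as.matrix(amounts)
  od <- flat %*% M[seq_len(ncol(flat)), , drop = FALSE]
  rgb <- 255 * 10^(-od)
  if (quantize) rgb <- clamp(round(rgb), 0, 255)
  if (length(d) == 3) array(rgb, c(d[1], d[2], 3)) else rgb
}

#' Colour deconvolution
#'
#' Inverts the Beer-Lambert mixing model: per-pixel stain amounts are
#' `M^-T %*% OD`. Negative amounts (noise, quantisation) are clipped to zero
#' and the clipped fraction is recorded.
#'
#' @param od OD array `H x W x 3` (from [rgb_to_od()]) or `N x 3` matrix.
#' @param M A [stain_matrix()].
#' @return `stain_channels`: array `H x W x 3` (or `N x 3`) of amounts with
#'   channel names and a `clip_fraction` attribute.
#' @export
deconvolve <- function(od, M) {
  if (!inherits(M, "stain_matrix")) M <- stain_matrix(M)
  d <- dim(od)
  flat <- if (length(d) == 3) matrix(od, d[1] * d[2], 3) else as.matrix(od)
  # per pixel OD (row) = amounts (row) %*% M, hence amounts = OD %*% M^-1
  amounts <- flat %*% solve(M)
  clip_fraction <- mean(amounts < -1e-12)
  amounts[amounts < 0] <- 0
  out <- if (length(d) == 3) array(amounts, c(d[1], d[2], 3)) else amounts
  structure(out, stains = rownames(M), clip_fraction = clip_fraction,
            class = c("stain_channels", class(out)))
}

#' Extract one stain channel
#' @param channels A `stain_channels` object from [deconvolve()].
#' @param stain Channel name or index.
#' @return Numeric matrix of per-pixel amounts for that stain.
#' @export
stain_channel <- function(channels, stain) {
  nm <- attr(channels, "stains")
  i <- if (is.character(stain)) match(stain, nm) else as.integer(stain)
  if (is.na(i)) abort(sprintf("unknown stain '%s'", stain))
  if (length(dim(channels)) == 3) channels[, , i] else channels[, i]
}

#' Positivity threshold from control regions
#'
#' Mirrors the control-region protocol: the threshold separating target
#' staining from background is derived from the mean stain amount of a
#' positively stained control region and of a background region. The declared
#' rule is the midpoint of the two means; `override` substitutes a manually
#' checked per-section value.
#'
#' @param channel Per-pixel stain-amount matrix.
#' @param positive_region,background_region Logical masks over `channel`.
#' @param override Optional manual threshold that replaces the rule.
#' @return Threshold in OD units.
#' @export
determine_threshold <- function(channel, positive_region, background_region,
                                override = NULL) {
  if (!is.null(override)) return(override)
  if (!any(positive_region) || !any(background_region)) {
    abort("control regions must be non-empty")
  }
  mp <- mean(channel[positive_region], na.rm = TRUE)
  mb <- mean(channel[background_region], na.rm = TRUE)
  if (!(mp > mb)) {
    abort("positive control mean does not exceed background mean")
  }
  (mp + mb) / 2
}

#' Per-pixel stain metric
#'
#' Converts a stain-amount channel into a percentage image. In `"area"` mode
#' a pixel is 100 if its amount reaches the threshold and 0 otherwise, so
#' block averages equal the positive-area fraction. In `"intensity"` mode
#' thresholded amounts are normalised to the 99th percentile of positive
#' amounts and scaled to 0-100. Pixels outside the tissue mask are `NA`.
#'
#' @param channel Per-pixel stain-amount matrix.
#' @param threshold Positivity threshold (OD units, >= 0).
#' @param tissue_mask Logical matrix of tissue pixels.
#' @param mode `"area"` (default) or `"intensity"`.
#' @return Matrix in `[0, 100]` with `NA` outside tissue; the mode is stored
#'   in the `"mode"` attribute.
#' @export
stain_metric <- function(channel, threshold, tissue_mask,
                         mode = c("area", "intensity")) {
  mode <- match.arg(mode)
  if (threshold < 0) abort("threshold must be >= 0")
  if (!any(tissue_mask)) abort("tissue mask is empty")
  pos <- channel >= threshold
  out <- matrix(NA_real_, nrow(channel), ncol(channel))
  if (mode == "area") {
    out[tissue_mask] <- 100 * as.numeric(pos[tissue_mask])
  } else {
    vals <- channel[tissue_mask & pos]
    ref <- if (length(vals)) stats::quantile(vals, 0.99, names = FALSE) else Inf
    x <- ifelse(pos, clamp(channel / ref, 0, 1) * 100, 0)
    out[tissue_mask] <- x[tissue_mask]
  }
  attr(out, "mode") <- mode
  out
}
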