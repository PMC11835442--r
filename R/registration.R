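#' 2D affine transform
#'
#' A 6-parameter map `p -> A p + t` between physical (micrometre) coordinate
#' frames. The linear part must be non-singular.
#'
#' @param A 2x2 linear part.
#' @param t Length-2 translation in micrometres.
#' @param from,to Frame tags; the analysis convention is `from = "mri"`,
#'   `to = "histology"` (the histology section is the fixed reference).
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(A, t = c(0, 0), from = "mri", to = "histology") {
  A <- matrix(as.numeric(A), 2, 2)
  t <- as.numeric(t)
  stopifnot(length(t) == 2)
  if (!all(is.finite(A)) || !all(is.finite(t))) abort("non-finite parameters")
  if (abs(det(A)) <= 1e-12) abort("linear part is singular")
  structure(list(A = A, t = t, from = from, to = to), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("<affine2d> %s -> %s\n", x$from, x$to))
  cat(sprintf("  A = [%8.4f %8.4f; %8.4f %8.4f],  t = (%.2f, %.2f) um\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$t[1], x$t[2]))
  invisible(x)
}

#' Build an affine from rotation/scale/shear/translation
#'
#' Convenience constructor: `A = R(theta) %*% diag(scale) %*% Shear(shear)`.
#'
#' @param rotation_deg Rotation angle in degrees (counter-clockwise).
#' @param scale Length-2 anisotropic scale factors.
#' @param shear Shear coefficient applied to the x axis.
#' @param translation_um Length-2 translation in micrometres.
#' @inheritParams affine2d
#' @return An `affine2d`.
#' @export
make_affine <- function(rotation_deg = 0, scale = c(1, 1), shear = 0,
                        translation_um = c(0, 0),
                        from = "mri", to = "histology") {
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- diag(rep(scale, length.out = 2))
  H <- matrix(c(1, 0, shear, 1), 2, 2)
  affine2d(R %*% S %*% H, translation_um, from = from, to = to)
}

#' Apply an affine transform to points
#'
#' @param transform An [affine2d()].
#' @param points A `landmark_set` or a 2-column matrix `(x, y)` in um.
#' @return Same shape as the input, transformed.
#' @export
apply_affine <- function(transform, points) {
  is_lm <- inherits(points, "landmark_set")
  xy <- if (is_lm) landmark_matrix(points) else as.matrix(points)
  out <- xy %*% t(transform$A)
  out[, 1] <- out[, 1] + transform$t[1]
  out[, 2] <- out[, 2] + transform$t[2]
  if (is_lm) landmark_set(out[, 1], out[, 2], frame = transform$to) else out
}

#' Invert an affine transform
#' @param transform An [affine2d()].
#' @return The inverse `affine2d` (frames swapped).
#' @export
invert_affine <- function(transform) {
  Ai <- solve(transform$A)
  affine2d(Ai, -as.vector(Ai %*% transform$t),
           from = transform$to, to = transform$from)
}

#' Estimate a 2D affine transform from paired landmarks
#'
#' Least-squares fit of `A, t` minimising `sum ||A s_i + t - d_i||^2` over
#' the point pairs. With exactly three non-collinear pairs the fit
#' interpolates. Fewer than 10 pairs triggers a warning because the manual
#' landmark protocol asks for at least 10.
#'
#' @param src Source landmarks (moving frame, typically MRI).
#' @param dst Destination landmarks (fixed frame, typically histology).
#' @return An [affine2d()] mapping src coordinates to dst coordinates.
#' @export
estimate_affine <- function(src, dst) {
  S <- if (inherits(src, "landmark_set")) landmark_matrix(src) else as.matrix(src)
  D <- if (inherits(dst, "landmark_set")) landmark_matrix(dst) else as.matrix(dst)
  if (nrow(S) != nrow(D)) abort("landmark sets are not paired (unequal sizes)")
  n <- nrow(S)
  if (n < 3) abort("at least 3 landmark pairs are required")
  if (n < 10) {
    warn(sprintf("only %d landmark pairs; the landmark protocol asks for >= 10", n))
  }
  if (points_collinear(S)) {
    abort("landmarks are collinear: affine parameters are not identifiable")
  }
  X <- cbind(S, 1)
  # QR least squares, one solve per output coordinate
  fit <- qr.coef(qr(X), D)
  A <- t(fit[1:2, , drop = FALSE])
  t <- as.numeric(fit[3, ])
  fr <- attr(src, "frame") %||% "mri"
  to <- attr(dst, "frame") %||% "histology"
  affine2d(A, t, from = fr, to = to)
}

#' Landmark registration error
#'
#' Root-mean-square residual, in micrometres, of a transform over paired
#' landmarks.
#'
#' @inheritParams estimate_affine
#' @param transform An [affine2d()].
#' @return RMSE in micrometres.
#' @export
registration_rmse <- function(transform, src, dst) {
  S <- if (inherits(src, "landmark_set")) landmark_matrix(src) else as.matrix(src)
  D <- if (inherits(dst, "landmark_set")) landmark_matrix(dst) else as.matrix(dst)
  stopifnot(nrow(S) == nrow(D))
  P <- apply_affine(transform, S)
  sqrt(mean(rowSums((P - D)^2)))
}

#' Warp an image onto a reference grid
#'
#' Inverse-mapping resampling: every pixel centre of the reference grid is
#' pulled back through the inverse transform into the moving image's physical
#' frame and interpolated there. Intensity images use bilinear interpolation,
#' label maps nearest-neighbour (labels are never averaged). Reference pixels
#' that fall outside the moving image are filled with `NA` and excluded from
#' all downstream aggregation.
#'
#' @param img An [mri_slice()] (intensities) or an integer label matrix with a
#'   known spacing given via `img_spacing_um`.
#' @param transform [affine2d()] mapping moving-frame to reference-frame
#'   coordinates.
#' @param reference A `grid_spec` or `mri_slice` defining the output grid.
#' @param interpolation `"bilinear"` or `"nearest"`; defaults to bilinear for
#'   `mri_slice` input and nearest for bare (label) matrices.
#' @param img_spacing_um Spacing of `img` when it is a bare matrix.
#' @return A matrix on the reference grid (`NA` outside the source field).
#' @export
warp_to_reference <- function(img, transform, reference,
                              interpolation = NULL, img_spacing_um = NULL) {
  ref <- as_grid_spec(reference)
  if (inherits(img, "mri_slice")) {
    values <- img$values
    sp <- img$spacing_um
    interpolation <- interpolation %||% "bilinear"
  } else {
    values <- img
    sp <- as.numeric(img_spacing_um)
    if (length(sp) == 1) sp <- rep(sp, 2)
    if (length(sp) != 2 || any(!is.finite(sp))) {
      abort("`img_spacing_um` is required when warping a bare matrix")
    }
    interpolation <- interpolation %||% "nearest"
  }
  inv <- invert_affine(transform)
  co <- grid_coords_um(ref)
  src <- cbind(co$x, co$y) %*% t(inv$A)
  src[, 1] <- src[, 1] + inv$t[1]
  src[, 2] <- src[, 2] + inv$t[2]
  rows <- src[, 2] / sp[1] + 1
  cols <- src[, 1] / sp[2] + 1
  out <- switch(interpolation,
    bilinear = sample_bilinear(values, rows, cols),
    nearest  = sample_nearest(values, rows, cols),
    abort("unknown interpolation scheme")
  )
  matrix(out, ref$dim[1], ref$dim[2])
}
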