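#' Landmark set
#'
#' An ordered set of 2D points in physical micrometre coordinates. Row order
#' is the pairing key between the MRI-frame and histology-frame sets.
#'
#' @param x_um,y_um Numeric coordinates in micrometres.
#' @param frame Coordinate frame tag (`"mri"` or `"histology"`).
#' @return A tibble of class `landmark_set` with columns `x_um`, `y_um`.
#' @export
landmark_set <- function(x_um, y_um, frame = "mri") {
  if (length(x_um) != length(y_um)) abort("coordinate vectors differ in length")
  if (length(x_um) < 3) abort("a landmark set needs at least 3 points")
  if (!all(is.finite(x_um)) || !all(is.finite(y_um))) {
    abort("landmark coordinates must be finite")
  }
  out <- tibble::tibble(x_um = as.numeric(x_um), y_um = as.numeric(y_um))
  class(out) <- c("landmark_set", class(out))
  attr(out, "frame") <- frame
  out
}

landmark_matrix <- function(lm) {
  cbind(x = lm$x_um, y = lm$y_um)
}

# TRUE when the point set is (numerically) collinear
points_collinear <- function(xy, tol = 1e-9) {
  xy <- sweep(xy, 2, colMeans(xy))
  s <- svd(xy, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}
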