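#' 2D MRI slice with physical spacing
#'
#' A thin matrix wrapper carrying the physical pixel size in micrometres, the
#' modality tag and the coordinate frame. Physical coordinates are
#' pixel-centre based and zero-based: the pixel in (row i, column j)
#' (1-based R indices) sits at `x = (j-1) * spacing_um[2]`,
#' `y = (i-1) * spacing_um[1]`.
#'
#' @param values Numeric matrix of signal values.
#' @param spacing_um Physical pixel size in micrometres; length 1 (isotropic)
#'   or 2 `(row, col)`.
#' @param modality Modality tag, e.g. `"FLAIR"` or `"T1"`.
#' @param subject_id Optional subject identifier.
#' @param frame Coordinate frame, `"mri"` or `"histology"`.
#' @return An object of class `mri_slice`.
#' @export
mri_slice <- function(values, spacing_um, modality = "FLAIR",
                      subject_id = NULL, frame = "mri") {
  if (!is.matrix(values)) abort("`values` must be a matrix")
  if (!all(is.finite(values) | is.na(values))) {
    abort("`values` contains non-finite entries")
  }
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 2)
  if (length(spacing_um) != 2 || any(!is.finite(spacing_um)) ||
      any(spacing_um <= 0)) {
    abort("`spacing_um` must be one or two positive finite numbers")
  }
  structure(
    list(values = values, spacing_um = spacing_um, modality = modality,
         subject_id = subject_id, frame = frame),
    class = "mri_slice"
  )
}

#' @export
print.mri_slice <- function(x, ...) {
  cat(sprintf("<mri_slice> %s, %d x %d px, %.0f x %.0f um/px, frame=%s\n",
              x$modality, nrow(x$values), ncol(x$values),
              x$spacing_um[1], x$spacing_um[2], x$frame))
  invisible(x)
}

#' @export
dim.mri_slice <- function(x) dim(x$values)

#' Reference grid specification
#'
#' Describes a pixel grid (image dimensions plus physical spacing) without
#' values; used as the fixed target of [warp_to_reference()].
#'
#' @param dim Integer vector `(rows, cols)`.
#' @param spacing_um Pixel size in micrometres (length 1 or 2).
#' @param frame Coordinate frame tag, default `"histology"`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(dim, spacing_um, frame = "histology") {
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 2)
  stopifnot(length(dim) == 2, all(dim >= 1), all(spacing_um > 0))
  structure(list(dim = as.integer(dim), spacing_um = spacing_um, frame = frame),
            class = "grid_spec")
}

as_grid_spec <- function(x) {
  if (inherits(x, "grid_spec")) return(x)
  if (inherits(x, "mri_slice")) {
    return(grid_spec(dim(x$values), x$spacing_um, frame = x$frame))
  }
  abort("cannot interpret object as a grid specification")
}

# physical pixel-centre coordinates of every pixel, column-major order
grid_coords_um <- function(grid) {
  grid <- as_grid_spec(grid)
  nr <- grid$dim[1]; nc <- grid$dim[2]
  list(
    x = rep((seq_len(nc) - 1) * grid$spacing_um[2], each = nr),
    y = rep((seq_len(nr) - 1) * grid$spacing_um[1], times = nc)
  )
}
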