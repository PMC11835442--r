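# On-disk formats: NIfTI for MRI slices, TIFF for stains and PLI stacks,
# TSV for landmarks and angles, CSV for block tables, YAML for parameters.
# Readers reject rather than guess when physical metadata is missing.

#' Write / read a 2D MRI slice as NIfTI
#'
#' The pixel spacing is stored in the NIfTI header (`pixdim`, millimetres);
#' reading a file whose header carries no usable (positive) spacing is an
#' error, never a silent default. 3D files require an explicit `slice` index.
#'
#' @param slice An [mri_slice()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mri_slice <- function(slice, path) {
  img <- RNifti::asNifti(slice$values)
  RNifti::pixdim(img) <- slice$spacing_um / 1000
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mri_slice
#' @param modality Modality tag to attach on read.
#' @param slice_index Index of the axial slice to extract from a 3D file.
#' @param subject_id Optional subject id to attach.
#' @export
read_mri_slice <- function(path, modality = "FLAIR", slice_index = NULL,
                           subject_id = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  vals <- if (length(d) == 2) {
    matrix(as.vector(img), d[1], d[2])
  } else if (length(d) == 3 && d[3] == 1) {
    matrix(img[, , 1], d[1], d[2])
  } else if (length(d) == 3) {
    if (is.null(slice_index)) {
      abort("3D volume: an explicit `slice_index` is required")
    }
    matrix(img[, , slice_index], d[1], d[2])
  } else {
    abort("only 2D slices or 3D volumes are supported")
  }
  sp_mm <- RNifti::pixdim(img)[1:2]
  if (any(!is.finite(sp_mm)) || any(sp_mm <= 0)) {
    abort("no usable pixel spacing in the NIfTI header; refusing to guess")
  }
  if (!all(is.finite(vals))) abort("non-finite voxel values")
  mri_slice(vals, sp_mm * 1000, modality = modality, subject_id = subject_id)
}

#' Write / read landmark TSV files
#'
#' Landmarks are stored one point per row with micrometre columns
#' `x_um`, `y_um`. Files using `x`, `y` plus a `unit` column (`um` or `mm`)
#' are converted on read. The two files of a pair must have equal row counts
#' (row order is the pairing key) and at least 3 rows.
#'
#' @param landmarks A [landmark_set()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.table(
    data.frame(x_um = sprintf("%.17g", landmarks$x_um),
               y_um = sprintf("%.17g", landmarks$y_um)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_landmark_file <- function(path, frame) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (all(c("x_um", "y_um") %in% names(d))) {
    x <- d$x_um; y <- d$y_um
  } else if (all(c("x", "y", "unit") %in% names(d))) {
    f <- ifelse(tolower(d$unit) == "mm", 1000,
                ifelse(tolower(d$unit) == "um", 1, NA))
    if (anyNA(f)) abort("unknown unit in landmark file (use 'um' or 'mm')")
    x <- d$x * f; y <- d$y * f
  } else {
    abort("landmark file needs columns x_um/y_um or x/y/unit")
  }
  if (length(x) < 3) abort("fewer than 3 landmarks")
  landmark_set(x, y, frame = frame)
}

#' @rdname write_landmarks
#' @param path_mri,path_hist Paths of the paired MRI- and histology-frame
#'   files.
#' @export
read_landmarks <- function(path_mri, path_hist) {
  mri <- read_landmark_file(path_mri, "mri")
  hist <- read_landmark_file(path_hist, "histology")
  if (nrow(mri) != nrow(hist)) {
    abort(sprintf("landmark pairing error: %d vs %d rows", nrow(mri),
                  nrow(hist)))
  }
  list(mri = mri, hist = hist)
}

analysis_table_schema <- c(
  "subject", "group", "roi", "segment", "block_row", "block_col",
  "flair_mean", "metric_name", "metric_value", "tissue_fraction", "included")

#' Write / read the block-level analysis table
#'
#' Fixed-schema CSV (comma separator, `.` decimal, header mandatory) with the
#' `included` flag serialised as 0/1. Numeric columns round-trip losslessly.
#'
#' @param table An `analysis_table` tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_analysis_table <- function(table, path) {
  miss <- setdiff(analysis_table_schema, names(table))
  if (length(miss)) {
    abort(paste("analysis table lacks columns:", paste(miss, collapse = ", ")))
  }
  out <- as.data.frame(table)[, analysis_table_schema]
  out$included <- as.integer(out$included)
  for (cc in c("flair_mean", "metric_value", "tissue_fraction")) {
    out[[cc]] <- sprintf("%.17g", out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_analysis_table
#' @export
read_analysis_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(d), analysis_table_schema)) {
    abort("schema mismatch: not an analysis table CSV")
  }
  d$included <- d$included != 0
  d$segment <- as.integer(d$segment)
  out <- tibble::as_tibble(d)
  class(out) <- c("analysis_table", class(out))
  out
}

#' Write / read an RGB stain image as TIFF
#'
#' 8-bit RGB TIFF; the micrometre-per-pixel size travels in a TSV sidecar
#' (`<path>.meta.tsv`). Reading an image without the sidecar is an error —
#' the pixel size is never guessed.
#'
#' @param rgb `H x W x 3` array on the 0-255 scale.
#' @param spacing_um Pixel size in micrometres.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_stain_tiff <- function(rgb, spacing_um, path) {
  tiff::writeTIFF(rgb / 255, path, bits.per.sample = 8, compression = "none")
  utils::write.table(data.frame(spacing_um = spacing_um),
                     paste0(path, ".meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stain_tiff
#' @export
read_stain_tiff <- function(path) {
  meta_path <- paste0(path, ".meta.tsv")
  if (!file.exists(meta_path)) {
    abort("stain TIFF has no spacing sidecar; pixel size unknown")
  }
  img <- tiff::readTIFF(path)
  meta <- utils::read.delim(meta_path)
  sp <- meta$spacing_um[1]
  if (!is.finite(sp) || sp <= 0) abort("invalid pixel size in sidecar")
  list(rgb = round(img * 255), spacing_um = sp)
}

#' Write / read a PLI rotation stack
#'
#' The intensity images are stored as one multi-page 32-bit float TIFF,
#' rescaled into `[0, 1]` by a recorded scale factor; rotation angles, the
#' scale and the pixel size live in a TSV sidecar (`<path>.angles.tsv`).
#'
#' @param stack A [pli_stack()].
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_pli_stack <- function(stack, path) {
  d <- dim(stack$images)
  scale <- max(abs(stack$images), 1e-12)
  pages <- lapply(seq_len(d[3]), function(k) {
    clamp(stack$images[, , k] / scale, 0, 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  utils::write.table(
    data.frame(angle_deg = stack$angles_deg,
               scale = sprintf("%.17g", scale),
               spacing_um = stack$spacing_um),
    paste0(path, ".angles.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pli_stack
#' @export
read_pli_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- utils::read.delim(paste0(path, ".angles.tsv"))
  if (length(pages) != nrow(side)) {
    abort("PLI stack pages and angle sidecar rows differ")
  }
  imgs <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) imgs[, , k] <- pages[[k]] * side$scale[1]
  pli_stack(imgs, side$angle_deg, side$spacing_um[1])
}

# flatten phantom parameters into a YAML-friendly list
params_to_list <- function(params) {
  p <- unclass(params)
  p$flair_means <- as.list(p$flair_means)
  p$t1_means <- as.list(p$t1_means)
  p$radii_frac <- as.list(p$radii_frac)
  p$group_effect <- as.list(p$group_effect)
  p
}

#' Write / read phantom parameters as YAML
#'
#' @param params A [phantom_params()].
#' @param path YAML path.
#' @return `path` (write) or a re-validated [phantom_params()] (read).
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(params_to_list(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- yaml::read_yaml(path)
  for (f in c("flair_means", "t1_means", "radii_frac", "group_effect")) {
    p[[f]] <- unlist(p[[f]])
  }
  do.call(phantom_params, p)
}

# write every artifact of one synthetic subject under `dir`
write_subject <- function(subject, dir, params) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mri_slice(subject$t1, file.path(dir, "t1.nii.gz"))
  write_mri_slice(subject$flair, file.path(dir, "flair.nii.gz"))
  lab <- mri_slice(subject$truth_labels + 0, subject$flair$spacing_um,
                   modality = "labels")
  write_mri_slice(lab, file.path(dir, "truth_labels.nii.gz"))
  write_stain_tiff(subject$lfb$rgb, params$hist_spacing_um,
                   file.path(dir, "lfb.tiff"))
  write_stain_tiff(subject$nfm$rgb, params$hist_spacing_um,
                   file.path(dir, "nfm.tiff"))
  png::writePNG(subject$lfb$tissue * 1, file.path(dir, "tissue_mask.png"))
  write_pli_stack(subject$pli_stack, file.path(dir, "pli_stack.tiff"))
  write_landmarks(subject$landmarks_mri, file.path(dir, "landmarks_mri.tsv"))
  write_landmarks(subject$landmarks_hist, file.path(dir, "landmarks_hist.tsv"))
  dir
}
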