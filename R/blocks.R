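#' Analysis block grid
#'
#' Tiles a co-registered image into square analysis blocks of physical side
#' `block_side_um` (default 400 um, i.e. 0.16 mm^2 area), the unit of
#' voxel-wise MRI-pathology correlation. The block side must be an integer
#' multiple of the pixel size; trailing partial rows/columns are dropped and
#' their count recorded.
#'
#' @param dim Image dimensions `(rows, cols)` in pixels.
#' @param spacing_um Pixel size in micrometres (length 1 or 2).
#' @param block_side_um Block side in micrometres (default 400).
#' @return Object of class `block_grid` with the block layout.
#' @export
make_block_grid <- function(dim, spacing_um, block_side_um = 400) {
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 2)
  if (block_side_um <= 0) abort("block side must be positive")
  px <- block_side_um / spacing_um
  if (any(abs(px - round(px)) > 1e-9)) {
    abort("block side must be an integer multiple of the pixel size; resample first")
  }
  px <- as.integer(round(px))
  n_rows <- dim[1] %/% px[1]
  n_cols <- dim[2] %/% px[2]
  if (n_rows < 1 || n_cols < 1) abort("image smaller than one block")
  structure(
    list(block_side_um = block_side_um, block_px = px,
         n_rows = n_rows, n_cols = n_cols,
         dropped_rows_px = dim[1] - n_rows * px[1],
         dropped_cols_px = dim[2] - n_cols * px[2],
         image_dim = as.integer(dim), spacing_um = spacing_um),
    class = "block_grid"
  )
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf(
    "<block_grid> %d x %d blocks of %.0f um (%d x %d px); dropped edge: %d px rows, %d px cols\n",
    x$n_rows, x$n_cols, x$block_side_um, x$block_px[1], x$block_px[2],
    x$dropped_rows_px, x$dropped_cols_px))
  invisible(x)
}

# integer block id per pixel (NA for dropped edge pixels), column-major
block_index <- function(grid) {
  r <- (seq_len(grid$image_dim[1]) - 1L) %/% grid$block_px[1]
  c <- (seq_len(grid$image_dim[2]) - 1L) %/% grid$block_px[2]
  r[r >= grid$n_rows] <- NA
  c[c >= grid$n_cols] <- NA
  outer(r, c, function(ri, ci) ri + ci * grid$n_rows + 1L)
}

# per-block sums of `img` (NA treated as missing) and counts of non-missing
# pixels, restricted to `mask` when given
block_stats <- function(img, grid, mask = NULL) {
  idx <- as.vector(block_index(grid))
  v <- as.vector(img)
  use <- !is.na(idx)
  if (!is.null(mask)) use <- use & as.vector(mask)
  ok <- use & !is.na(v)
  nb <- grid$n_rows * grid$n_cols
  sums <- rep(0, nb); cnts <- rep(0L, nb)
  if (any(ok)) {
    s <- rowsum(v[ok], idx[ok])
    n <- rowsum(rep(1L, sum(ok)), idx[ok])
    ids <- as.integer(rownames(s))
    sums[ids] <- s[, 1]
    cnts[ids] <- n[, 1]
  }
  list(sum = sums, n = cnts)
}

#' Aggregate a metric image into blocks
#'
#' Computes per block the mean of the metric over tissue-valid pixels, the
#' tissue fraction, and the inclusion flag. A block is included when at least
#' 50% of its pixels contain tissue (blocks with *less than* 50% tissue are
#' excluded; exactly 50% is included). Blocks without any tissue pixel get an
#' undefined (`NA`) mean and are excluded.
#'
#' @param img Numeric metric image (`NA` allowed for invalid pixels).
#' @param tissue_mask Logical matrix marking tissue (vs background, ventricle
#'   or out-of-field) pixels.
#' @param grid A [make_block_grid()] on the same image dimensions.
#' @param min_tissue Inclusion threshold on the tissue fraction (default 0.5).
#' @return Tibble with columns `block_row`, `block_col` (0-based), `mean`,
#'   `tissue_fraction`, `included`.
#' @export
aggregate_blocks <- function(img, tissue_mask, grid, min_tissue = 0.5) {
  stopifnot(all(dim(img) == grid$image_dim), all(dim(tissue_mask) == grid$image_dim))
  valid <- tissue_mask & !is.na(img)
  st <- block_stats(img, grid, mask = valid)
  block_area <- prod(grid$block_px)
  # tissue_fraction counts tissue pixels with a usable (non-NA) metric value
  tfv <- st$n / block_area
  nb <- grid$n_rows * grid$n_cols
  ids <- seq_len(nb) - 1L
  tibble::tibble(
    block_row = ids %% grid$n_rows,
    block_col = ids %/% grid$n_rows,
    mean = ifelse(st$n > 0, st$sum / pmax(st$n, 1), NA_real_),
    tissue_fraction = tfv,
    included = tfv >= min_tissue
  )
}

#' Join block-level MRI signal, ROI, segment and pathology metrics
#'
#' Builds the per-block analysis table on the common histology reference
#' grid. For each retained block: `flair_mean` is the mean registered FLAIR
#' signal over tissue pixels; the ROI is the majority label among NAWM/WMH
#' pixels (blocks whose valid pixels are mostly GM/background are dropped;
#' NAWM wins ties); the segment is the majority graded label among the ROI's
#' pixels (ties to the lower segment). One row is emitted per retained,
#' tissue-included block and metric.
#'
#' @param flair_reg Registered FLAIR image on the reference grid.
#' @param seg_reg Registered segmentation labels (0 bg, 1 GM, 2 NAWM, 3 WMH).
#' @param graded A `graded_map` from [grade_rois()] on the same grid.
#' @param metrics Named list of metric images (percent scale) on the grid.
#' @param tissue_mask Logical tissue matrix on the grid.
#' @param grid A [make_block_grid()].
#' @param subject,group Identifiers copied into every row.
#' @param min_tissue Inclusion threshold (default 0.5).
#' @return `analysis_table` tibble with columns `subject`, `group`, `roi`,
#'   `segment`, `block_row`, `block_col`, `flair_mean`, `metric_name`,
#'   `metric_value`, `tissue_fraction`, `included`.
#' @export
join_blocks <- function(flair_reg, seg_reg, graded, metrics, tissue_mask,
                        grid, subject = "s", group = "control",
                        min_tissue = 0.5) {
  dims <- grid$image_dim
  for (m in metrics) stopifnot(all(dim(m) == dims))
  stopifnot(all(dim(flair_reg) == dims), all(dim(seg_reg) == dims))

  flair_blocks <- aggregate_blocks(flair_reg, tissue_mask, grid, min_tissue)
  nb <- nrow(flair_blocks)

  # majority votes via per-label block counts
  count_label <- function(mask) block_stats(mask * 1, grid)$sum
  seg_ok <- !is.na(seg_reg)
  n_valid <- count_label(tissue_mask & seg_ok)
  n_nawm <- count_label(tissue_mask & seg_ok & seg_reg == 2)
  n_wmh <- count_label(tissue_mask & seg_ok & seg_reg == 3)
  wm_majority <- (n_nawm + n_wmh) > 0.5 * pmax(n_valid, 1) & n_valid > 0
  roi <- ifelse(n_wmh > n_nawm, "WMH", "NAWM") # ties -> NAWM

  seg_lab <- matrix(NA_integer_, dims[1], dims[2])
  seg_lab[graded$nawm > 0] <- graded$nawm[graded$nawm > 0]
  seg_lab[graded$wmh > 0] <- graded$wmh[graded$wmh > 0]
  segment <- integer(nb)
  seg_counts <- vapply(1:3, function(s) {
    roi_code <- ifelse(roi == "WMH", 3L, 2L)
    # count graded label s within the block's winning ROI
    cnt_w <- count_label(seg_ok & seg_reg == 3 & !is.na(seg_lab) & seg_lab == s)
    cnt_n <- count_label(seg_ok & seg_reg == 2 & !is.na(seg_lab) & seg_lab == s)
    ifelse(roi_code == 3L, cnt_w, cnt_n)
  }, numeric(nb))
  segment <- max.col(seg_counts, ties.method = "first")

  keep <- flair_blocks$included & wm_majority
  rows <- purrr::map(names(metrics), function(nm) {
    mb <- aggregate_blocks(metrics[[nm]], tissue_mask, grid, min_tissue)
    tibble::tibble(
      subject = subject, group = group,
      roi = roi, segment = as.integer(segment),
      block_row = flair_blocks$block_row, block_col = flair_blocks$block_col,
      flair_mean = flair_blocks$mean,
      metric_name = nm, metric_value = mb$mean,
      tissue_fraction = flair_blocks$tissue_fraction,
      included = keep & mb$included
    )[keep & mb$included & !is.na(mb$mean), ]
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("analysis_table", class(out))
  out
}

#' Render a block-level heatmap
#'
#' Places the block means of one metric back onto the block grid; excluded or
#' absent blocks take the reserved masked value `NA`. Cell values equal the
#' table values exactly (no smoothing).
#'
#' @param table An `analysis_table` (or any tibble with `block_row`,
#'   `block_col`, `metric_name`, `metric_value`).
#' @param grid The [make_block_grid()] the table was built on.
#' @param metric Metric name to render.
#' @return Matrix `n_rows x n_cols` of class `block_heatmap` (`NA` = masked)
#'   with the metric name and block size as attributes.
#' @export
render_heatmap <- function(table, grid, metric) {
  if (!metric %in% table$metric_name) abort(sprintf("unknown metric '%s'", metric))
  tb <- table[table$metric_name == metric & table$included, ]
  m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  m[cbind(tb$block_row + 1L, tb$block_col + 1L)] <- tb$metric_value
  structure(m, metric = metric, block_side_um = grid$block_side_um,
            class = c("block_heatmap", "matrix"))
}

#' @rdname render_heatmap
#' @param object A `block_heatmap`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.block_heatmap <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$value <- object[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  name = attr(object, "metric")) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("block column (%.0f um)", attr(object, "block_side_um")),
      y = "block row",
      title = sprintf("%s block heatmap", attr(object, "metric"))) +
    ggplot2::theme_minimal()
}
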