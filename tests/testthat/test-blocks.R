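test_that("block grids tile the image with the 0.16 mm^2 geometry", {
  g <- make_block_grid(c(80, 80), 20, 400)
  expect_equal(c(g$n_rows, g$n_cols), c(4L, 4L))
  expect_equal(g$block_px, c(20L, 20L))
  expect_equal(g$block_side_um^2 / 1e6, 0.16) # 400 um square = 0.16 mm^2
  g2 <- make_block_grid(c(90, 80), 20, 400)
  expect_equal(c(g2$n_rows, g2$n_cols), c(4L, 4L))
  expect_equal(g2$dropped_rows_px, 10L)
  expect_error(make_block_grid(c(80, 80), 30, 400), "integer multiple")
})

test_that("block means equal a brute-force double loop exactly", {
  set.seed(3)
  img <- matrix(rnorm(60 * 40), 60, 40)
  tissue <- matrix(runif(60 * 40) > 0.3, 60, 40)
  g <- make_block_grid(c(60, 40), 50, 500) # 10 x 10 px blocks
  got <- aggregate_blocks(img, tissue, g)
  for (br in 0:(g$n_rows - 1)) {
    for (bc in 0:(g$n_cols - 1)) {
      rr <- (br * 10 + 1):(br * 10 + 10)
      cc <- (bc * 10 + 1):(bc * 10 + 10)
      sel <- tissue[rr, cc]
      expected <- if (any(sel)) mean(img[rr, cc][sel]) else NA_real_
      row <- got[got$block_row == br & got$block_col == bc, ]
      expect_equal(row$mean, expected, tolerance = 1e-12)
      expect_identical(row$tissue_fraction, mean(sel))
      expect_identical(row$included, mean(sel) >= 0.5)
    }
  }
})

test_that("the inclusion boundary follows the strict less-than-50% rule", {
  img <- matrix(1, 20, 20)
  g <- make_block_grid(c(20, 20), 20, 400) # one 400-pixel block
  t199 <- matrix(FALSE, 20, 20); t199[seq_len(199)] <- TRUE
  t200 <- matrix(FALSE, 20, 20); t200[seq_len(200)] <- TRUE
  expect_false(aggregate_blocks(img, t199, g)$included)
  expect_equal(aggregate_blocks(img, t199, g)$tissue_fraction, 0.4975)
  expect_true(aggregate_blocks(img, t200, g)$included) # exactly 50% stays
  # mean conservation on a constant image with full tissue
  full <- aggregate_blocks(matrix(7, 20, 20), matrix(TRUE, 20, 20), g)
  expect_equal(full$mean, 7)
  expect_equal(full$tissue_fraction, 1)
})

test_that("join_blocks applies majority votes for ROI and segment", {
  n <- 20 # two 10x10-px blocks side by side
  g <- make_block_grid(c(10, n), 40, 400)
  seg <- matrix(2L, 10, n)
  seg[, 1:4] <- 3L # block 1: 40% WMH -> NAWM majority
  seg[, 11:17] <- 3L # block 2: 70% WMH -> WMH majority
  flair <- matrix(100, 10, n)
  graded <- structure(list(
    wmh = ifelse(seg == 3L, 3L, 0L),
    nawm = ifelse(seg == 2L, 1L, 0L),
    centroids = list()), class = "graded_map")
  tissue <- matrix(TRUE, 10, n)
  tab <- join_blocks(flair, seg, graded, list(M = matrix(50, 10, n)), tissue,
                     g, subject = "s", group = "control")
  tab <- dplyr::arrange(tab, block_col)
  expect_equal(tab$roi, c("NAWM", "WMH"))
  expect_equal(tab$segment, c(1L, 3L))
  expect_equal(tab$flair_mean, c(100, 100))
  expect_equal(tab$metric_value, c(50, 50))
})

test_that("blocks dominated by GM or background are dropped", {
  g <- make_block_grid(c(10, 10), 40, 400)
  seg <- matrix(1L, 10, 10) # 100% GM
  graded <- structure(list(wmh = matrix(0L, 10, 10),
                           nawm = matrix(0L, 10, 10), centroids = list()),
                      class = "graded_map")
  tab <- join_blocks(matrix(1, 10, 10), seg, graded,
                     list(M = matrix(1, 10, 10)), matrix(TRUE, 10, 10), g)
  expect_equal(nrow(tab), 0)
})

test_that("heatmap cells equal table values exactly with masking", {
  tab <- fixture_table()
  grid <- attr(tab, "block_grid")
  hm <- render_heatmap(tab, grid, "LFB")
  sub <- tab[tab$metric_name == "LFB" & tab$included, ]
  expect_equal(hm[cbind(sub$block_row + 1, sub$block_col + 1)],
               sub$metric_value)
  # cells without an included block are the reserved masked value
  expect_equal(sum(!is.na(hm)), nrow(sub))
  expect_error(render_heatmap(tab, grid, "nope"), "unknown metric")
  pl <- ggplot2::autoplot(hm)
  expect_s3_class(pl, "ggplot")
})
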