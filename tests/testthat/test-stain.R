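test_that("optical density transform matches Beer-Lambert arithmetic", {
  white <- array(255, c(1, 1, 3))
  expect_equal(as.vector(rgb_to_od(white)), rep(0, 3), tolerance = 2e-3)
  # intensity 25 -> OD -log10(26/255), about 1 per channel
  grey <- array(25, c(1, 1, 3))
  expect_equal(as.vector(rgb_to_od(grey)), rep(-log10(26 / 255), 3))
  expect_equal(as.vector(rgb_to_od(grey)), rep(1, 3), tolerance = 0.01)
  # OD additivity of two stains
  M <- stain_matrix(list(dab = stain_vector("dab"),
                         hematoxylin = stain_vector("hematoxylin")))
  od1 <- 0.3 * unclass(M)[1, ]
  od2 <- 0.5 * unclass(M)[2, ]
  rgb12 <- 255 * 10^-(od1 + od2)
  expect_equal(as.vector(rgb_to_od(matrix(rgb12, 1, 3), eps = 0)),
               unname(od1 + od2))
  expect_error(rgb_to_od(matrix(1, 2, 2)), "3 array")
})

test_that("deconvolution inverts the forward model", {
  M <- stain_matrix(list(dab = stain_vector("dab"),
                         hematoxylin = stain_vector("hematoxylin")))
  # float path: exact inverse
  a <- matrix(c(0.7, 0, 0), 1, 3)
  od <- a %*% unclass(M)
  rec <- deconvolve(od, M)
  expect_equal(as.vector(rec), c(0.7, 0, 0), tolerance = 1e-6)
  blank <- deconvolve(matrix(0, 1, 3), M)
  expect_true(all(blank == 0))
  # a padded single-stain matrix is still invertible
  M1 <- stain_matrix(list(lfb = stain_vector("lfb")))
  expect_equal(unname(rowSums(unclass(M1)^2)), rep(1, 3))
  expect_gt(abs(det(unclass(M1))), 0.5)
  expect_error(stain_matrix(list(a = c(1, 0, 0), b = c(2, 0, 0))),
               "dependent")
})

test_that("clipping of negative amounts is recorded", {
  M <- stain_matrix(list(lfb = stain_vector("lfb")))
  od <- matrix(c(-0.05, 0.02, 0.01), 1, 3) # slightly negative OD (noise)
  rec <- deconvolve(od, M)
  expect_true(all(rec >= 0))
  expect_gt(attr(rec, "clip_fraction"), 0)
})

test_that("control-region threshold follows the midpoint rule", {
  ch <- matrix(c(rep(0.8, 10), rep(0.1, 10)), 4, 5)
  pos <- ch > 0.5
  bg <- !pos
  expect_equal(determine_threshold(ch, pos, bg), 0.45)
  expect_equal(determine_threshold(ch, pos, bg, override = 0.3), 0.3)
  expect_error(determine_threshold(ch, bg, pos), "exceed")
  # monotone in the background mean
  ch2 <- ch
  ch2[bg] <- 0.3
  expect_gt(determine_threshold(ch2, pos, bg), 0.45)
})

test_that("stain metrics are bounded and equal the positive-area fraction", {
  set.seed(9)
  ch <- matrix(runif(400), 20, 20)
  tissue <- matrix(TRUE, 20, 20)
  m0 <- stain_metric(ch, threshold = 2, tissue_mask = tissue)
  expect_true(all(m0 == 0))
  m100 <- stain_metric(ch, threshold = 0, tissue_mask = tissue)
  expect_true(all(m100 == 100))
  # half-positive two-level phantom: area metric mean is exactly 50%
  two <- matrix(rep(c(0.2, 0.8), each = 200), 20, 20)
  ma <- stain_metric(two, threshold = 0.5, tissue_mask = tissue, mode = "area")
  expect_equal(mean(ma), 50)
  expect_equal(mean(ma), 100 * mean(two >= 0.5)) # direct-count oracle
  mi <- stain_metric(ch, threshold = 0.3, tissue_mask = tissue,
                     mode = "intensity")
  expect_true(all(mi >= 0 & mi <= 100))
  expect_true(all(mi[ch < 0.3] == 0))
  expect_error(stain_metric(ch, 0.5, matrix(FALSE, 20, 20)), "empty")
})

test_that("8-bit quantisation keeps the round trip within 2%", {
  set.seed(14)
  M <- stain_matrix(list(dab = stain_vector("dab"),
                         hematoxylin = stain_vector("hematoxylin")))
  amounts <- cbind(runif(2000, 0, 0.4), runif(2000, 0, 0.4), 0)
  rgb <- stains_to_rgb(amounts, M, quantize = TRUE)
  rec <- deconvolve(rgb_to_od(rgb), M)
  expect_lt(max(abs(rec[, 1:2] - amounts[, 1:2])), 0.02)
})
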