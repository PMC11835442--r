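test_that("estimate_affine recovers exact and trivial correspondences", {
  set.seed(4)
  src <- cbind(runif(10, 0, 20000), runif(10, 0, 20000))
  expect_warning(e3 <- estimate_affine(src[1:4, ], src[1:4, ]), ">= 10")
  est <- estimate_affine(src, src)
  expect_equal(est$A, diag(2), tolerance = 1e-10)
  expect_equal(est$t, c(0, 0), tolerance = 1e-7)
  dst <- sweep(src, 2, c(300, -200), "+")
  est2 <- estimate_affine(src, dst)
  expect_equal(est2$A, diag(2), tolerance = 1e-10)
  expect_equal(est2$t, c(300, -200), tolerance = 1e-7)
  bad <- cbind(1:5, 2 * (1:5) + 3)
  expect_error(suppressWarnings(estimate_affine(bad, bad)), "collinear")
})

test_that("least-squares fit agrees with the normal-equations oracle under jitter", {
  set.seed(11)
  ta <- make_affine(12, c(1.08, 0.93), 0.04, c(800, -350))
  src <- cbind(runif(12, 0, 20000), runif(12, 0, 20000))
  dst <- apply_affine(ta, src) + matrix(rnorm(24, 0, 40), 12, 2)
  est <- estimate_affine(src, dst)
  orc <- affine_normal_equations(src, dst)
  expect_equal(est$A, orc$A, tolerance = 1e-9)
  expect_equal(est$t, orc$t, tolerance = 1e-9)
})

test_that("registration_rmse matches closed forms", {
  src <- cbind(runif(10, 0, 10000), runif(10, 0, 10000))
  ident <- affine2d(diag(2), c(0, 0))
  expect_equal(registration_rmse(ident, src, src), 0)
  dst <- src
  dst[1, 1] <- dst[1, 1] + 1000 # single 1 mm outlier among 10 exact pairs
  expect_equal(registration_rmse(ident, src, dst), 1000 / sqrt(10),
               tolerance = 1e-12)
})

test_that("warping is exact for identity and integer-pixel translations", {
  img <- mri_slice(matrix(rnorm(400), 20, 20), 100, "FLAIR")
  grid <- grid_spec(c(20, 20), 100, "histology")
  ident <- affine2d(diag(2), c(0, 0))
  expect_equal(warp_to_reference(img, ident, grid), img$values)
  # translation by exactly 3 pixels: pure index shift, no interpolation blur
  tr <- affine2d(diag(2), c(300, 0))
  w <- warp_to_reference(img, tr, grid)
  expect_equal(w[, 4:20], img$values[, 1:17])
  expect_true(all(is.na(w[, 1:3])))
})

test_that("label warps never invent labels and constants are conserved", {
  set.seed(21)
  for (i in 1:5) {
    lab <- matrix(sample(0:3, 400, TRUE), 20, 20)
    ta <- make_affine(runif(1, -30, 30), runif(2, 0.8, 1.2),
                      runif(1, -0.1, 0.1), runif(2, -500, 500))
    w <- warp_to_reference(lab, ta, grid_spec(c(25, 25), 80, "histology"),
                           img_spacing_um = 100)
    expect_true(all(stats::na.omit(unique(as.vector(w))) %in% 0:3))
  }
  cst <- mri_slice(matrix(7, 20, 20), 100, "FLAIR")
  ta <- make_affine(13, c(1.05, 0.97), 0.02, c(120, -80))
  w <- warp_to_reference(cst, ta, grid_spec(c(20, 20), 100, "histology"))
  expect_true(all(abs(w[!is.na(w)] - 7) < 1e-12))
  expect_gt(sum(!is.na(w)), 0)
})

test_that("estimate-then-apply reproduces the generating transform", {
  set.seed(8)
  src <- cbind(runif(10, 0, 15000), runif(10, 0, 15000))
  ta <- make_affine(-20, c(0.9, 1.15), -0.06, c(-400, 900))
  dst <- apply_affine(ta, src)
  est <- estimate_affine(src, dst)
  expect_equal(apply_affine(est, src), dst, tolerance = 1e-9)
  # affine-only contract: a 2x2 linear part plus translation, nothing else
  expect_equal(dim(est$A), c(2L, 2L))
  expect_length(est$t, 2)
  expect_error(affine2d(matrix(0, 2, 2), c(0, 0)), "singular")
})
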