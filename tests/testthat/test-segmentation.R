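test_that("augmentation is identity when off and involutive for flips", {
  set.seed(2)
  x <- array(rnorm(32), c(4, 4, 2))
  lab <- matrix(sample(0:3, 16, TRUE), 4, 4)
  off <- augment(x, lab, flip = FALSE, rotate = FALSE, intensity_jitter = 0,
                 seed = 1)
  expect_identical(off$x, x)
  expect_identical(off$labels, lab)
  # flipping twice restores the original
  flip_once <- function(a) a[rev(seq_len(nrow(a))), , , drop = FALSE]
  expect_identical(flip_once(flip_once(x)), x)
  # geometric augmentation never invents labels
  for (sd in 1:10) {
    out <- augment(x, lab, flip = TRUE, rotate = TRUE, intensity_jitter = 0,
                   seed = sd)
    expect_setequal(unique(as.vector(out$labels)), unique(as.vector(lab)))
    # images and labels move together: label-conditioned means unchanged
    for (k in unique(as.vector(lab))) {
      expect_equal(mean(out$x[, , 1][out$labels == k]),
                   mean(x[, , 1][lab == k]))
    }
  }
})

test_that("probability maps average and collapse as defined", {
  expect_equal(probabilities_to_labels(
    array(c(0.1, 0.2, 0.3, 0.4), c(1, 1, 4)))[1, 1], 3L)
  expect_equal(probabilities_to_labels(
    array(0.25, c(1, 1, 4)))[1, 1], 0L) # exact tie -> background
  onehot <- array(0, c(2, 2, 4))
  lab <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  for (i in 1:2) for (j in 1:2) onehot[i, j, lab[i, j] + 1] <- 1
  expect_identical(probabilities_to_labels(onehot), lab)
})

test_that("dice scores match hand-counted overlaps", {
  a <- matrix(0L, 4, 5); a[2:3, 2:3] <- 1L
  b <- matrix(0L, 4, 5); b[2:3, 3:4] <- 1L
  d <- dice_per_class(a, b, classes = 1)
  expect_equal(unname(d), 2 * 2 / (4 + 4)) # |A.B| = 2 -> 0.5
  expect_equal(unname(dice_per_class(a, a, classes = 0:1)), c(1, 1))
  dis <- matrix(0L, 2, 2); dis2 <- matrix(0L, 2, 2)
  dis[1, 1] <- 1L; dis2[2, 2] <- 1L
  expect_equal(unname(dice_per_class(dis, dis2, classes = 1)), 0)
  # class absent from both maps scores 1 by convention
  expect_equal(unname(dice_per_class(dis, dis2, classes = 3)), 1)
  expect_error(dice_per_class(a, matrix(0L, 2, 2)), "shape")
})

test_that("a tiny ensemble trains, averages and stays normalised", {
  set.seed(31)
  mk <- function(i) {
    lab <- matrix(0L, 16, 16)
    lab[, 9:16] <- 3L
    x <- array(0, c(16, 16, 2))
    x[, , 1] <- 50 + matrix(rnorm(256, 0, 3), 16, 16)
    x[, , 2] <- ifelse(lab == 3L, 150, 60) + matrix(rnorm(256, 0, 3), 16, 16)
    list(x = x, labels = lab)
  }
  pairs <- lapply(1:3, mk)
  cfg <- unet_config(n_members = 2, base_channels = 4, depth = 2, epochs = 8,
                     seed = 3)
  ens <- train_ensemble(lapply(pairs, `[[`, "x"),
                        lapply(pairs, `[[`, "labels"), cfg)
  g <- glance(ens)
  expect_lt(g$loss_final, g$loss_first) # training reduces the loss
  # members start from pairwise different initialisations
  w1 <- ens$members[[1]]$enc[[1]]$conv1$W
  w2 <- ens$members[[2]]$enc[[1]]$conv1$W
  expect_gt(max(abs(w1 - w2)), 0)
  # ensemble mean equals the average of single-member predictions
  x <- pairs[[1]]$x
  p_ens <- predict_ensemble(ens, x)
  one <- function(i) structure(list(members = ens$members[i], config = cfg),
                               class = "unet_ensemble")
  p1 <- predict_ensemble(one(1), x)
  p2 <- predict_ensemble(one(2), x)
  expect_equal(unclass(p_ens), (unclass(p1) + unclass(p2)) / 2,
               tolerance = 1e-12)
  # a one-member ensemble is that member (mean of one)
  expect_equal(unclass(predict_ensemble(one(1), x)), unclass(p1))
  # probability conservation at every pixel
  sums <- apply(p_ens, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(p_ens >= 0))
  # determinism: retraining with the same config reproduces the weights
  ens2 <- train_ensemble(lapply(pairs, `[[`, "x"),
                         lapply(pairs, `[[`, "labels"), cfg)
  expect_identical(ens$members[[1]]$final$W, ens2$members[[1]]$final$W)
})

test_that("degenerate constant inputs raise a warning", {
  x <- array(0, c(16, 16, 2))
  lab <- matrix(0L, 16, 16)
  cfg <- unet_config(n_members = 1, base_channels = 2, depth = 2, epochs = 1,
                     seed = 1)
  expect_warning(train_ensemble(list(x), list(lab), cfg), "degenerate")
})

test_that("training stacks resample T1 onto the FLAIR grid", {
  s <- fixture_subject()
  st <- subject_to_training(s)
  expect_equal(dim(st$x)[1:2], dim(s$flair$values))
  expect_identical(st$labels, s$truth_labels)
  # T1 channel keeps the tissue contrast after resampling
  expect_gt(mean(st$x[, , 1][st$labels == 2]),
            mean(st$x[, , 1][st$labels == 0]))
})
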