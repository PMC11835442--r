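#' Configuration of the segmentation U-Net ensemble
#'
#' @param n_members Number of ensemble members (>= 1, default 3).
#' @param base_channels Feature channels at full resolution (default 8).
#' @param depth Number of pooling levels (default 3).
#' @param epochs Training epochs (>= 1).
#' @param lr Adam learning rate.
#' @param dice_weight Weight of the soft-Dice term added to cross-entropy.
#' @param in_channels Input channels (2: T1 + FLAIR).
#' @param n_classes Output classes (4: background, GM, NAWM, WMH).
#' @param intensity_scale Intensities are divided by this before entering the
#'   network.
#' @param augment List of switches: `flip`, `rotate` (right-angle rotations)
#'   and `intensity_jitter` (SD of multiplicative gain jitter; 0 disables).
#' @param seed Master seed; member initialisations and augmentation streams
#'   derive from it.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(n_members = 3, base_channels = 8, depth = 3,
                        epochs = 40, lr = 2e-3, dice_weight = 1,
                        in_channels = 2, n_classes = 4,
                        intensity_scale = 200,
                        augment = list(flip = TRUE, rotate = TRUE,
                                       intensity_jitter = 0.05),
                        seed = 1) {
  if (n_members < 1) abort("n_members must be >= 1")
  if (epochs < 1) abort("epochs must be >= 1")
  structure(as.list(environment()), class = "unet_config")
}

#' Jointly augment an image pair and its label map
#'
#' Geometric transforms (horizontal/vertical flips, right-angle rotations)
#' are applied identically to the image channels and the labels; labels use
#' exact index permutation (nearest-neighbour, no interpolation, no new
#' labels). Intensity jitter (multiplicative gain plus offset) touches the
#' images only. With all switches off the input is returned unchanged.
#'
#' @param x `H x W x C` image array.
#' @param labels Integer label matrix congruent with `x`.
#' @param flip,rotate Logical switches.
#' @param intensity_jitter SD of the jitter (0 disables).
#' @param seed Seed for the random draws.
#' @return List with transformed `x` and `labels`.
#' @export
augment <- function(x, labels, flip = TRUE, rotate = TRUE,
                    intensity_jitter = 0.05, seed = 1) {
  stopifnot(all(dim(x)[1:2] == dim(labels)))
  with_seed(derive_seed(seed, "augment"), {
    if (flip && runif(1) < 0.5) {
      x <- x[rev(seq_len(nrow(labels))), , , drop = FALSE]
      labels <- labels[rev(seq_len(nrow(labels))), , drop = FALSE]
    }
    if (flip && runif(1) < 0.5) {
      x <- x[, rev(seq_len(ncol(labels))), , drop = FALSE]
      labels <- labels[, rev(seq_len(ncol(labels))), drop = FALSE]
    }
    if (rotate) {
      k <- sample(0:3, 1)
      if (k > 0 && nrow(labels) == ncol(labels)) {
        rot90a <- function(a) {
          aperm(a, c(2, 1, 3))[rev(seq_len(ncol(a))), , , drop = FALSE]
        }
        rot90m <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
        for (i in seq_len(k)) {
          x <- rot90a(x)
          labels <- rot90m(labels)
        }
      }
    }
    if (intensity_jitter > 0) {
      for (cch in seq_len(dim(x)[3])) {
        gain <- exp(rnorm(1, 0, intensity_jitter))
        offs <- rnorm(1, 0, intensity_jitter)
        x[, , cch] <- x[, , cch] * gain + offs
      }
    }
  })
  list(x = x, labels = labels)
}

#' Build a two-channel training stack from a synthetic subject
#'
#' Stacks T1 (bilinearly resampled onto the FLAIR grid, where the truth
#' labels are defined) with FLAIR into an `H x W x 2` array.
#'
#' @param subject A `wmh_subject`.
#' @return List with `x` (input stack) and `labels` (truth matrix).
#' @export
subject_to_training <- function(subject) {
  fg <- grid_spec(dim(subject$flair$values), subject$flair$spacing_um, "mri")
  ident <- affine2d(diag(2), c(0, 0), from = "mri", to = "mri")
  t1r <- warp_to_reference(subject$t1, ident, fg, "bilinear")
  t1r[is.na(t1r)] <- 0
  d <- dim(subject$flair$values)
  list(x = array(c(t1r, subject$flair$values), c(d, 2)),
       labels = subject$truth_labels)
}

#' Train the U-Net segmentation ensemble
#'
#' Each member starts from its own seed-derived initialisation and is trained
#' with Adam on the summed cross-entropy + soft-Dice loss, with on-the-fly
#' augmentation. Training is deterministic given `config$seed`. Constant
#' (zero-variance) inputs raise a degenerate-input warning; a non-finite loss
#' aborts with diagnostics.
#'
#' @param inputs List of `H x W x 2` arrays (T1, FLAIR channels).
#' @param labels List of congruent integer truth matrices (codes 0-3).
#' @param config A [unet_config()].
#' @return Object of class `unet_ensemble` with members, config and a
#'   per-epoch loss `history`; see [glance()].
#' @export
train_ensemble <- function(inputs, labels, config = unet_config()) {
  stopifnot(length(inputs) >= 1, length(inputs) == length(labels))
  if (all(vapply(inputs, function(x) var(as.vector(x)) == 0, logical(1)))) {
    warn("degenerate input: all training images are constant")
  }
  history <- list()
  members <- vector("list", config$n_members)
  for (m in seq_len(config$n_members)) {
    member <- unet_init_member(config, derive_seed(config$seed, "init", m))
    flat <- unet_flatten(member)
    state <- adam_init(flat)
    t_step <- 0
    for (ep in seq_len(config$epochs)) {
      ord <- with_seed(derive_seed(config$seed, "order", m, ep), {
        sample(seq_along(inputs))
      })
      ep_loss <- 0
      for (s in ord) {
        aug <- augment(inputs[[s]], labels[[s]],
                       flip = isTRUE(config$augment$flip),
                       rotate = isTRUE(config$augment$rotate),
                       intensity_jitter = config$augment$intensity_jitter %||% 0,
                       seed = derive_seed(config$seed, "aug", m, ep, s))
        x <- aug$x / config$intensity_scale
        fw <- unet_forward(member, x, train = TRUE)
        ls <- unet_loss(fw$logits, aug$labels, config$n_classes,
                        config$dice_weight)
        if (!is.finite(ls$loss)) {
          abort(sprintf(
            "non-finite loss (member %d, epoch %d, sample %d): lower lr or rescale inputs",
            m, ep, s))
        }
        ep_loss <- ep_loss + ls$loss
        grads <- unet_flatten(unet_backward(member, fw, ls$dz))
        t_step <- t_step + 1
        upd <- adam_step(flat, grads, state, config$lr, t_step)
        flat <- upd$par
        state <- upd$state
        member <- unet_unflatten(flat, member)
      }
      history[[length(history) + 1]] <-
        tibble::tibble(member = m, epoch = ep,
                       loss = ep_loss / length(inputs))
    }
    members[[m]] <- member
  }
  structure(list(members = members, config = config,
                 history = dplyr::bind_rows(history)),
            class = "unet_ensemble")
}

#' @export
print.unet_ensemble <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<unet_ensemble> %d member(s), depth %d, base %d ch, %d epochs; final mean loss %.4f\n",
    length(x$members), x$config$depth, x$config$base_channels,
    x$config$epochs, mean(h$loss[h$epoch == max(h$epoch)])))
  invisible(x)
}

#' Training summary of an ensemble
#' @param x A `unet_ensemble`.
#' @param ... Unused.
#' @return One-row tibble with first/final mean training loss.
#' @exportS3Method generics::glance
glance.unet_ensemble <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_members = length(x$members),
    epochs = x$config$epochs,
    loss_first = mean(h$loss[h$epoch == 1]),
    loss_final = mean(h$loss[h$epoch == max(h$epoch)])
  )
}

#' Predict the ensemble probability map
#'
#' Runs every member and averages the per-pixel class probabilities
#' arithmetically; the result is a four-channel probability map whose pixel
#' vectors are non-negative and sum to one.
#'
#' @param model A `unet_ensemble` (or a single member inside one).
#' @param x `H x W x 2` input stack (raw intensity scale).
#' @return `H x W x K` probability array of class `prob_map`.
#' @export
predict_ensemble <- function(model, x) {
  cfg <- model$config
  if (!all(dim(x)[3] == cfg$in_channels)) abort("input channel mismatch")
  if (any(dim(x)[1:2] %% 2^cfg$depth != 0)) {
    abort(sprintf("image sides must be multiples of %d for depth %d",
                  2^cfg$depth, cfg$depth))
  }
  xs <- x / cfg$intensity_scale
  maps <- lapply(model$members, function(mem) {
    fw <- unet_forward(mem, xs, train = FALSE)
    array(softmax_rows(fw$logits), c(fw$dim, cfg$n_classes))
  })
  avg <- Reduce(`+`, maps) / length(maps)
  structure(avg, class = c("prob_map", class(avg)))
}

#' Collapse a probability map to labels
#'
#' Per-pixel argmax over the fixed class order (background, GM, NAWM, WMH);
#' exact ties resolve to the lowest class index (never invents lesion).
#'
#' @param prob `H x W x K` probability array.
#' @return Integer label matrix with codes 0-3.
#' @export
probabilities_to_labels <- function(prob) {
  d <- dim(prob)
  flat <- matrix(prob, d[1] * d[2], d[3])
  matrix(max.col(flat, ties.method = "first") - 1L, d[1], d[2])
}

#' Dice overlap per class
#'
#' `Dice = 2 |A . B| / (|A| + |B|)` for each label code; a class absent from
#' both maps scores 1 by convention.
#'
#' @param pred,truth Congruent integer label matrices.
#' @param classes Label codes to score (default 0-3).
#' @return Named numeric vector of Dice scores.
#' @export
dice_per_class <- function(pred, truth, classes = 0:3) {
  if (!all(dim(pred) == dim(truth))) abort("label maps differ in shape")
  out <- vapply(classes, function(k) {
    a <- pred == k
    b <- truth == k
    s <- sum(a) + sum(b)
    if (s == 0) 1 else 2 * sum(a & b) / s
  }, numeric(1))
  names(out) <- c("background", "GM", "NAWM", "WMH")[match(classes, 0:3)]
  out
}
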