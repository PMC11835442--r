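# U-Net member: parameter construction, forward/backward pass and the
# cross-entropy + soft-Dice loss. Class order is fixed as
# (background, GM, NAWM, WMH).

unet_channels <- function(config) {
  config$base_channels * 2^(0:config$depth)
}

unet_init_member <- function(config, seed) {
  with_seed(seed, {
    d <- config$depth
    ch <- unet_channels(config)
    enc <- lapply(seq_len(d), function(i) {
      cin <- if (i == 1) config$in_channels else ch[i - 1]
      list(conv1 = conv_init(cin, ch[i]), conv2 = conv_init(ch[i], ch[i]))
    })
    bott <- list(conv1 = conv_init(ch[d], ch[d + 1]),
                 conv2 = conv_init(ch[d + 1], ch[d + 1]))
    dec <- lapply(seq_len(d), function(i) {
      list(up = conv_init(ch[i + 1], ch[i]),
           conv1 = conv_init(2 * ch[i], ch[i]),
           conv2 = conv_init(ch[i], ch[i]))
    })
    final <- list(W = matrix(rnorm(ch[1] * config$n_classes, 0,
                                   sqrt(2 / ch[1])),
                             ch[1], config$n_classes),
                  b = rep(0, config$n_classes))
    list(enc = enc, bott = bott, dec = dec, final = final)
  })
}

# forward pass; returns logits (H*W x K) and, when train = TRUE, all caches
unet_forward <- function(member, x, train = FALSE) {
  d <- length(member$enc)
  caches <- list(enc = vector("list", d), dec = vector("list", d))
  skips <- vector("list", d)
  cur <- x
  for (i in seq_len(d)) {
    c1 <- conv_forward(cur, member$enc[[i]]$conv1)
    r1 <- relu_forward(c1$out)
    c2 <- conv_forward(r1$out, member$enc[[i]]$conv2)
    r2 <- relu_forward(c2$out)
    skips[[i]] <- r2$out
    mp <- maxpool_forward(r2$out)
    cur <- mp$out
    if (train) caches$enc[[i]] <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, mp = mp)
  }
  b1 <- conv_forward(cur, member$bott$conv1)
  br1 <- relu_forward(b1$out)
  b2 <- conv_forward(br1$out, member$bott$conv2)
  br2 <- relu_forward(b2$out)
  cur <- br2$out
  if (train) caches$bott <- list(b1 = b1, br1 = br1, b2 = b2, br2 = br2)
  for (i in rev(seq_len(d))) {
    up <- upsample_forward(cur)
    u <- conv_forward(up, member$dec[[i]]$up)
    ur <- relu_forward(u$out)
    cat <- concat_channels(skips[[i]], ur$out)
    c1 <- conv_forward(cat, member$dec[[i]]$conv1)
    r1 <- relu_forward(c1$out)
    c2 <- conv_forward(r1$out, member$dec[[i]]$conv2)
    r2 <- relu_forward(c2$out)
    cur <- r2$out
    if (train) caches$dec[[i]] <- list(u = u, ur = ur, c1 = c1, r1 = r1,
                                       c2 = c2, r2 = r2,
                                       skip_ch = dim(skips[[i]])[3])
  }
  dd <- dim(cur)
  flat <- matrix(cur, dd[1] * dd[2], dd[3])
  logits <- flat %*% member$final$W
  logits <- logits + matrix(member$final$b, nrow(logits), ncol(logits),
                            byrow = TRUE)
  if (train) caches$final <- list(flat = flat, dim = dd)
  list(logits = logits, dim = dd[1:2], caches = if (train) caches else NULL)
}

# backward pass from d(logits); returns gradients in the member's shape
unet_backward <- function(member, fw, dz) {
  caches <- fw$caches
  d <- length(member$enc)
  grads <- list(enc = vector("list", d), dec = vector("list", d))
  fin <- caches$final
  grads$final <- list(W = crossprod(fin$flat, dz), b = colSums(dz))
  dflat <- dz %*% t(member$final$W)
  dcur <- array(dflat, fin$dim)
  for (i in seq_len(d)) { # decoder levels in forward-completion order (1..d)
    cc <- caches$dec[[i]]
    dr2 <- relu_backward(dcur, cc$r2$cache)
    g2 <- conv_backward(dr2, member$dec[[i]]$conv2, cc$c2$cache)
    dr1 <- relu_backward(g2$dx, cc$r1$cache)
    g1 <- conv_backward(dr1, member$dec[[i]]$conv1, cc$c1$cache)
    sc <- cc$skip_ch
    dskip <- g1$dx[, , seq_len(sc), drop = FALSE]
    dur <- g1$dx[, , -seq_len(sc), drop = FALSE]
    du <- relu_backward(dur, cc$ur$cache)
    gu <- conv_backward(du, member$dec[[i]]$up, cc$u$cache)
    dcur <- upsample_backward(gu$dx)
    grads$dec[[i]] <- list(up = list(W = gu$dW, b = gu$db),
                           conv1 = list(W = g1$dW, b = g1$db),
                           conv2 = list(W = g2$dW, b = g2$db))
    grads$dskip[[i]] <- dskip
  }
  bb <- caches$bott
  dbr2 <- relu_backward(dcur, bb$br2$cache)
  gb2 <- conv_backward(dbr2, member$bott$conv2, bb$b2$cache)
  dbr1 <- relu_backward(gb2$dx, bb$br1$cache)
  gb1 <- conv_backward(dbr1, member$bott$conv1, bb$b1$cache)
  grads$bott <- list(conv1 = list(W = gb1$dW, b = gb1$db),
                     conv2 = list(W = gb2$dW, b = gb2$db))
  dcur <- gb1$dx
  for (i in rev(seq_len(d))) {
    ec <- caches$enc[[i]]
    dpool <- maxpool_backward(dcur, ec$mp$cache)
    dpool <- dpool + grads$dskip[[i]] # skip connection contribution
    dr2 <- relu_backward(dpool, ec$r2$cache)
    g2 <- conv_backward(dr2, member$enc[[i]]$conv2, ec$c2$cache)
    dr1 <- relu_backward(g2$dx, ec$r1$cache)
    g1 <- conv_backward(dr1, member$enc[[i]]$conv1, ec$c1$cache)
    dcur <- g1$dx
    grads$enc[[i]] <- list(conv1 = list(W = g1$dW, b = g1$db),
                           conv2 = list(W = g2$dW, b = g2$db))
  }
  grads$dskip <- NULL
  grads
}

# cross-entropy + soft-Dice loss on logits; returns loss value and d(logits)
unet_loss <- function(logits, labels, n_classes, dice_weight = 1) {
  n <- nrow(logits)
  tmat <- matrix(0, n, n_classes)
  tmat[cbind(seq_len(n), as.vector(labels) + 1L)] <- 1
  p <- softmax_rows(logits)
  ce <- -mean(log(p[tmat == 1] + 1e-12))
  A <- colSums(p * tmat)
  B <- colSums(p) + colSums(tmat) + 1e-12
  dice <- 2 * A / B
  loss <- ce + dice_weight * (1 - mean(dice))
  dz_ce <- (p - tmat) / n
  gp <- -sweep(sweep(tmat, 2, 2 / B, "*"), 2, 2 * A / B^2, "-") / n_classes
  dz_dice <- p * (gp - rowSums(gp * p))
  list(loss = loss, dz = dz_ce + dice_weight * dz_dice, dice = dice)
}

# flatten nested parameter lists for the optimiser
unet_flatten <- function(params, prefix = "") {
  out <- list()
  nms <- names(params) %||% as.character(seq_along(params))
  for (j in seq_along(params)) {
    nm <- nms[j]
    p <- params[[j]]
    key <- paste0(prefix, nm)
    if (is.list(p) && !all(c("W", "b") %in% names(p))) {
      out <- c(out, unet_flatten(p, paste0(key, ".")))
    } else if (is.list(p)) {
      out[[paste0(key, ".W")]] <- p$W
      out[[paste0(key, ".b")]] <- p$b
    }
  }
  out
}

unet_unflatten <- function(flat, template, prefix = "") {
  nms <- names(template) %||% as.character(seq_along(template))
  for (j in seq_along(template)) {
    p <- template[[j]]
    key <- paste0(prefix, nms[j])
    if (is.list(p) && !all(c("W", "b") %in% names(p))) {
      template[[j]] <- unet_unflatten(flat, p, paste0(key, "."))
    } else if (is.list(p)) {
      template[[j]]$W <- flat[[paste0(key, ".W")]]
      template[[j]]$b <- flat[[paste0(key, ".b")]]
    }
  }
  template
}
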