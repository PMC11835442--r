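# Minimal CPU neural-network layers for the segmentation U-Net.
# Tensors are H x W x C arrays; convolutions use im2col + BLAS matmul.
# Everything is deterministic given the R RNG state.

im2col3 <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  cols <- vector("list", 9)
  k <- 1
  for (dc in 0:2) {
    for (dr in 0:2) {
      cols[[k]] <- matrix(xp[(1:H) + dr, (1:W) + dc, , drop = FALSE], H * W, C)
      k <- k + 1
    }
  }
  do.call(cbind, cols) # (H*W) x (9*C), offset-major blocks
}

col2im3 <- function(dcols, H, W, C) {
  dxp <- array(0, c(H + 2, W + 2, C))
  k <- 1
  for (dc in 0:2) {
    for (dr in 0:2) {
      blk <- array(dcols[, ((k - 1) * C + 1):(k * C)], c(H, W, C))
      dxp[(1:H) + dr, (1:W) + dc, ] <- dxp[(1:H) + dr, (1:W) + dc, ] + blk
      k <- k + 1
    }
  }
  dxp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

conv_init <- function(c_in, c_out, gain = 2) {
  # He-normal fan-in initialisation for ReLU networks
  list(W = matrix(rnorm(9 * c_in * c_out, 0, sqrt(gain / (9 * c_in))),
                  9 * c_in, c_out),
       b = rep(0, c_out))
}

conv_forward <- function(x, par) {
  d <- dim(x)
  Xc <- im2col3(x)
  y <- Xc %*% par$W
  y <- y + matrix(par$b, nrow(y), ncol(y), byrow = TRUE)
  list(out = array(y, c(d[1], d[2], ncol(par$W))),
       cache = list(Xc = Xc, dim = d))
}

conv_backward <- function(dy, par, cache) {
  d <- cache$dim
  dy_m <- matrix(dy, d[1] * d[2], length(par$b))
  dW <- crossprod(cache$Xc, dy_m)
  db <- colSums(dy_m)
  dXc <- dy_m %*% t(par$W)
  dx <- col2im3(dXc, d[1], d[2], d[3])
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

maxpool_forward <- function(x) {
  d <- dim(x)
  ri <- seq(1, d[1], 2); ci <- seq(1, d[2], 2)
  a <- x[ri, ci, , drop = FALSE]
  b <- x[ri + 1, ci, , drop = FALSE]
  cc <- x[ri, ci + 1, , drop = FALSE]
  dd <- x[ri + 1, ci + 1, , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  # deterministic winner: first of (a, b, c, d) attaining the max
  wa <- a == y
  wb <- b == y & !wa
  wc <- cc == y & !wa & !wb
  wd <- !wa & !wb & !wc
  list(out = y, cache = list(wa = wa, wb = wb, wc = wc, wd = wd, dim = d))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dim
  dx <- array(0, d)
  ri <- seq(1, d[1], 2); ci <- seq(1, d[2], 2)
  dx[ri, ci, ] <- dy * cache$wa
  dx[ri + 1, ci, ] <- dy * cache$wb
  dx[ri, ci + 1, ] <- dy * cache$wc
  dx[ri + 1, ci + 1, ] <- dy * cache$wd
  dx
}

upsample_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

upsample_backward <- function(dy) {
  d <- dim(dy)
  ri <- seq(1, d[1], 2); ci <- seq(1, d[2], 2)
  dy[ri, ci, , drop = FALSE] + dy[ri + 1, ci, , drop = FALSE] +
    dy[ri, ci + 1, , drop = FALSE] + dy[ri + 1, ci + 1, , drop = FALSE]
}

concat_channels <- function(a, b) {
  d <- dim(a)
  array(c(a, b), c(d[1], d[2], d[3] + dim(b)[3]))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Adam parameter update, state threaded through
adam_step <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(par)) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(par = par, state = state)
}

adam_init <- function(par) {
  zero <- lapply(par, function(p) p * 0)
  list(m = zero, v = zero)
}
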