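#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm runif sd var
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible child seed
#'
#' Hashes a master seed together with string/integer labels into a new seed in
#' `[1, 2^31 - 2]`, so that independent stages of a pipeline draw from
#' independent, reproducible streams.
#'
#' @param seed Integer master seed.
#' @param ... Further labels (character or integer) identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  labels <- unlist(lapply(list(...), function(l) {
    if (is.character(l)) utf8ToInt(paste(l, collapse = "")) else as.integer(l)
  }))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (v in labels) {
    h <- (h * 48271 + as.numeric(v) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# run expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# moving-window box sum of a matrix (window odd), edge windows truncated.
# NA values are treated as 0; use together with a count of valid pixels.
box_sum <- function(m, window) {
  stopifnot(window %% 2 == 1, window >= 1)
  if (window > nrow(m) || window > ncol(m)) {
    abort("window larger than image")
  }
  h <- (window - 1L) / 2L
  m[is.na(m)] <- 0
  # summed-area table with a zero top row/left column
  sat <- rbind(0, apply(m, 2, cumsum))
  sat <- cbind(0, t(apply(sat, 1, cumsum)))
  nr <- nrow(m); nc <- ncol(m)
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  R1 <- matrix(r1, nr, nc); R2 <- matrix(r2, nr, nc)
  C1 <- matrix(c1, nr, nc, byrow = TRUE); C2 <- matrix(c2, nr, nc, byrow = TRUE)
  idx <- function(r, c) sat[cbind(as.vector(r), as.vector(c))]
  out <- idx(R2 + 1L, C2 + 1L) - idx(R1, C2 + 1L) - idx(R2 + 1L, C1) + idx(R1, C1)
  matrix(out, nr, nc)
}

# bilinear interpolation of `values` at fractional (row, col) R indices;
# NA outside the grid.
sample_bilinear <- function(values, row, col) {
  nr <- nrow(values); nc <- ncol(values)
  out <- rep(NA_real_, length(row))
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc &
    is.finite(row) & is.finite(col)
  if (!any(ok)) return(out)
  r <- row[ok]; c <- col[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  v00 <- values[cbind(r0, c0)]
  v01 <- values[cbind(r0, c0 + 1L)]
  v10 <- values[cbind(r0 + 1L, c0)]
  v11 <- values[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
  out
}

# nearest-neighbour sampling; NA outside the grid (half-pixel border included)
sample_nearest <- function(values, row, col) {
  nr <- nrow(values); nc <- ncol(values)
  out <- rep(values[1] * NA, length(row))
  ri <- round(row); ci <- round(col)
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc & is.finite(ri) & is.finite(ci)
  if (any(ok)) out[ok] <- values[cbind(ri[ok], ci[ok])]
  out
}
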