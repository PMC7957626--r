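# Internal numerical helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All randomness in the package goes through
# this so that library calls never perturb user RNG state.
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
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed from a parent seed and a fixed stream offset,
# keeping everything inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647L)
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

relu <- function(x) {
  d <- dim(x)
  x <- pmax(x, 0)
  dim(x) <- d
  x
}

# Bilinear resampling of a matrix to (h_out, w_out), half-pixel-center
# convention (src = (dst + 0.5) * scale - 0.5), edge-clamped.
bilinear_resize_matrix <- function(m, h_out, w_out) {
  h <- nrow(m)
  w <- ncol(m)
  if (h_out == h && w_out == w) return(m)
  sy <- (seq_len(h_out) - 0.5) * h / h_out - 0.5
  sx <- (seq_len(w_out) - 0.5) * w / w_out - 0.5
  y0 <- pmin(pmax(floor(sy), 0), h - 1)
  x0 <- pmin(pmax(floor(sx), 0), w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  x1 <- pmin(x0 + 1, w - 1)
  fy <- pmin(pmax(sy - y0, 0), 1)
  fx <- pmin(pmax(sx - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE]
  b <- m[y0 + 1, x1 + 1, drop = FALSE]
  cc <- m[y1 + 1, x0 + 1, drop = FALSE]
  d <- m[y1 + 1, x1 + 1, drop = FALSE]
  wfy <- matrix(fy, h_out, w_out)
  wfx <- matrix(fx, h_out, w_out, byrow = TRUE)
  top <- a * (1 - wfx) + b * wfx
  bot <- cc * (1 - wfx) + d * wfx
  top * (1 - wfy) + bot * wfy
}

bilinear_resize_image <- function(img, h_out, w_out) {
  out <- array(0, c(h_out, w_out, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- bilinear_resize_matrix(img[, , ch], h_out, w_out)
  }
  out
}

# Nearest-neighbour upsampling by index replication; exact (mean-preserving)
# for integer scale factors.
upsample_nearest <- function(x, h_out, w_out) {
  hs <- dim(x)[1]
  ws <- dim(x)[2]
  ri <- floor((seq_len(h_out) - 1) * hs / h_out) + 1
  ci <- floor((seq_len(w_out) - 1) * ws / w_out) + 1
  x[ri, ci, , drop = FALSE]
}

# 3x3 convolution, stride 2, reflective "same" padding, so that the output
# spatial size is ceiling(input / 2). Reflection (not zero) padding keeps
# border cells statistically comparable to interior cells, so downstream
# magnitude-based saliency is free of constant border spikes. Implemented as
# im2col + one matrix product.
# x: h x w x cin, w_arr: 3 x 3 x cin x cout, b: length cout.
conv3x3_stride2 <- function(x, w_arr, b) {
  h <- dim(x)[1]
  w <- dim(x)[2]
  cin <- dim(x)[3]
  cout <- dim(w_arr)[4]
  ho <- ceiling(h / 2)
  wo <- ceiling(w / 2)
  xp <- array(0, c(h + 2L, w + 2L, cin))
  xp[2:(h + 1L), 2:(w + 1L), ] <- x
  # mirror rows/cols (edge excluded) into the one-cell border
  xp[1L, 2:(w + 1L), ] <- x[min(2L, h), , ]
  xp[h + 2L, 2:(w + 1L), ] <- x[max(h - 1L, 1L), , ]
  xp[2:(h + 1L), 1L, ] <- x[, min(2L, w), ]
  xp[2:(h + 1L), w + 2L, ] <- x[, max(w - 1L, 1L), ]
  xp[1L, 1L, ] <- x[min(2L, h), min(2L, w), ]
  xp[1L, w + 2L, ] <- x[min(2L, h), max(w - 1L, 1L), ]
  xp[h + 2L, 1L, ] <- x[max(h - 1L, 1L), min(2L, w), ]
  xp[h + 2L, w + 2L, ] <- x[max(h - 1L, 1L), max(w - 1L, 1L), ]
  cols <- matrix(0, ho * wo, 9L * cin)
  wm <- matrix(0, 9L * cin, cout)
  k <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      k <- k + 1L
      ri <- seq.int(1L + di, by = 2L, length.out = ho)
      ci <- seq.int(1L + dj, by = 2L, length.out = wo)
      blk <- xp[ri, ci, , drop = FALSE]
      cols[, ((k - 1L) * cin + 1L):(k * cin)] <- matrix(blk, ho * wo, cin)
      wm[((k - 1L) * cin + 1L):(k * cin), ] <- w_arr[di + 1L, dj + 1L, , ]
    }
  }
  out <- cols %*% wm
  out <- sweep(out, 2L, b, "+")
  array(out, c(ho, wo, cout))
}

# Euclidean disc membership helper used by the generator and the pointing game.
disc_mask <- function(h, w, cy, cx, r) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

is_binary_mask <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}
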