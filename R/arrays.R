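# Internal array plumbing.
#
# Layout conventions used throughout the package:
#   images       : array [H, W, N]          (N = batch)
#   feature maps : array [oh, ow, N, C]     (C = channels)
# Convolutions are "valid" (no padding) and implemented as im2col followed by
# a BLAS matrix product; the denominator average pooling is a separable box
# filter with zero padding ("same" output, fixed 1/pool^2 weight so border
# pixels are under-pooled).

# Extract valid-convolution patches: returns matrix [oh*ow*N, k*k] whose
# rows follow the [oh, ow, N] layout.
im2col <- function(images, k) {
  d <- dim(images)
  H <- d[1]; W <- d[2]; N <- d[3]
  oh <- H - k + 1L; ow <- W - k + 1L
  stopifnot(oh >= 1, ow >= 1)
  out <- matrix(0, oh * ow * N, k * k)
  col <- 1L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      out[, col] <- as.vector(images[di:(di + oh - 1L), dj:(dj + ow - 1L), ,
                                     drop = FALSE])
      col <- col + 1L
    }
  }
  out
}

# Valid convolution (really cross-correlation, the deep-learning convention)
# of images with a filter bank w [k, k, C]. Returns [oh, ow, N, C].
conv_valid <- function(images, w) {
  k <- dim(w)[1]
  stopifnot(dim(w)[2] == k)
  d <- dim(images)
  oh <- d[1] - k + 1L; ow <- d[2] - k + 1L
  patches <- im2col(images, k)
  wmat <- matrix(w, k * k, dim(w)[3])
  out <- patches %*% wmat
  dim(out) <- c(oh, ow, d[3], dim(w)[3])
  out
}

# Banded matrix applying a length-`size` centered box sum with zero padding
# along one dimension of length n. Symmetric, hence self-adjoint.
box_band <- function(n, size) {
  half <- (size - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    B[i, j] <- 1
  }
  B
}

# Cache of sparse 2D pooling operators keyed by (oh, ow, size).
.pool_cache <- new.env(parent = emptyenv())

# Sparse [oh*ow, oh*ow] matrix of the zero-padded box average (symmetric).
pool_operator <- function(oh, ow, size) {
  key <- paste(oh, ow, size, sep = "x")
  P <- .pool_cache[[key]]
  if (is.null(P)) {
    P <- Matrix::Matrix(kronecker(box_band(ow, size), box_band(oh, size)) /
                          size^2, sparse = TRUE)
    .pool_cache[[key]] <- P
  }
  P
}

# 5x5 (or `size`^2) spatial average pooling, stride 1, zero-padded "same"
# output, fixed divisor size^2. Operates on [oh, ow, N, C].
avg_pool_same <- function(maps, size) {
  d <- dim(maps)
  P <- pool_operator(d[1], d[2], size)
  x <- as.matrix(P %*% matrix(maps, d[1] * d[2], d[3] * d[4]))
  dim(x) <- d
  x
}

# Symmetric crop of the two leading spatial dims by `margin` px per side.
crop_sym <- function(maps, margin) {
  if (margin == 0L) return(maps)
  d <- dim(maps)
  maps[(margin + 1L):(d[1] - margin), (margin + 1L):(d[2] - margin), , ,
       drop = FALSE]
}

# Adjoint of crop_sym: zero-pad back to the uncropped spatial size.
uncrop_sym <- function(maps, margin, full_dim) {
  if (margin == 0L) return(maps)
  out <- array(0, full_dim)
  d <- dim(maps)
  out[(margin + 1L):(margin + d[1]), (margin + 1L):(margin + d[2]), , ] <- maps
  out
}

# Per-channel power y^n for maps [oh, ow, N, C], n length C, y >= 0.
pow_channels <- function(maps, n) {
  d <- dim(maps)
  m <- matrix(maps, prod(d[1:3]), d[4])
  out <- sweep_pow(m, n)
  dim(out) <- d
  out
}

sweep_pow <- function(m, n) {
  out <- m
  for (c in seq_along(n)) out[, c] <- m[, c]^n[c]
  out
}

# Matrix view [oh*ow*N, C] of a feature-map array (cheap: C is last dim).
fm_mat <- function(maps) {
  d <- dim(maps)
  dim(maps) <- c(prod(d[1:3]), d[4])
  maps
}

fm_arr <- function(m, d) {
  dim(m) <- d
  m
}
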