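# Low-level neural primitives for 4D activation tensors stored as R arrays
# with dims (channels, depth, height, width). Convolutions are evaluated as
# im2col + BLAS matrix multiply; everything is deterministic in eval mode.

# Zero-pad the three spatial axes of a (C,D,H,W) array by p voxels each side.
pad_spatial <- function(x, p, value = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(value, dim = c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4] + 2 * p))
  out[, p + seq_len(d[2]), p + seq_len(d[3]), p + seq_len(d[4])] <- x
  out
}

conv_out_len <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1

# im2col: unfold k^3 patches of the padded input into a (Cin*k^3) x Ncells
# matrix whose row order matches the column-major flattening of weight dims
# (Cin, k, k, k).
im2col3d <- function(x, k, stride, pad) {
  xp <- pad_spatial(x, pad)
  d <- dim(xp)
  C <- d[1]
  Do <- conv_out_len(dim(x)[2], k, stride, pad)
  Ho <- conv_out_len(dim(x)[3], k, stride, pad)
  Wo <- conv_out_len(dim(x)[4], k, stride, pad)
  assert_that(Do >= 1 && Ho >= 1 && Wo >= 1,
              "spatial input too small for this kernel/stride",
              "gliofuse_size_error")
  d0 <- seq(1, by = stride, length.out = Do)
  h0 <- seq(1, by = stride, length.out = Ho)
  w0 <- seq(1, by = stride, length.out = Wo)
  ncell <- Do * Ho * Wo
  X <- matrix(0, C * k^3, ncell)
  row <- 0L
  for (cc in seq_len(k)) for (bb in seq_len(k)) for (aa in seq_len(k)) {
    blk <- xp[, d0 + aa - 1, h0 + bb - 1, w0 + cc - 1, drop = FALSE]
    X[row + seq_len(C), ] <- matrix(blk, C, ncell)
    row <- row + C
  }
  attr(X, "out_dims") <- c(Do, Ho, Wo)
  X
}

# 3D convolution. weights: array (Cout, Cin, k, k, k); bias: length Cout.
conv3d <- function(x, weights, bias = NULL, stride = 1L, pad = 0L) {
  wd <- dim(weights)
  assert_that(dim(x)[1] == wd[2], "channel mismatch in conv3d",
              "gliofuse_dimension_error")
  k <- wd[3]
  X <- im2col3d(x, k, stride, pad)
  W <- matrix(weights, wd[1], wd[2] * k^3)
  out <- W %*% X
  if (!is.null(bias)) out <- out + bias
  array(out, dim = c(wd[1], attr(X, "out_dims")))
}

# Per-channel batch normalization. With running statistics absent (the frozen
# random-feature regime) the per-volume spatial statistics are used instead,
# which keeps activation scales stable through deep stacks and stays fully
# deterministic.
batchnorm3d <- function(x, gamma, beta, running_mean = NULL,
                        running_var = NULL, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, d[1])
  if (is.null(running_mean)) {
    mu <- rowMeans(m)
    v <- rowMeans(m^2) - mu^2
  } else {
    mu <- running_mean
    v <- running_var
  }
  m <- (m - mu) / sqrt(v + eps) * gamma + beta
  array(m, dim = d)
}

# Pooling over non-overlapping/strided windows via the same unfold trick.
pool3d <- function(x, k, stride, pad = 0L, type = c("max", "avg")) {
  type <- match.arg(type)
  d <- dim(x)
  xp <- pad_spatial(x, pad, value = if (type == "max") -Inf else 0)
  Do <- conv_out_len(d[2], k, stride, pad)
  Ho <- conv_out_len(d[3], k, stride, pad)
  Wo <- conv_out_len(d[4], k, stride, pad)
  assert_that(Do >= 1 && Ho >= 1 && Wo >= 1,
              "spatial input too small to pool", "gliofuse_size_error")
  d0 <- seq(1, by = stride, length.out = Do)
  h0 <- seq(1, by = stride, length.out = Ho)
  w0 <- seq(1, by = stride, length.out = Wo)
  acc <- NULL
  cnt <- 0L
  for (cc in seq_len(k)) for (bb in seq_len(k)) for (aa in seq_len(k)) {
    blk <- xp[, d0 + aa - 1, h0 + bb - 1, w0 + cc - 1, drop = FALSE]
    acc <- if (is.null(acc)) blk else if (type == "max") pmax(acc, blk) else acc + blk
    cnt <- cnt + 1L
  }
  if (type == "avg") acc <- acc / cnt
  array(acc, dim = c(d[1], Do, Ho, Wo))
}

# Averaging matrix for adaptive average pooling along one axis: bin i covers
# input indices floor((i-1)*n/S)+1 .. ceiling(i*n/S); bins overlap when
# upsampling (n < S) so no bin is ever empty.
adaptive_bins_matrix <- function(n, S) {
  W <- matrix(0, S, n)
  for (i in seq_len(S)) {
    a <- floor((i - 1) * n / S) + 1
    b <- ceiling(i * n / S)
    W[i, a:b] <- 1 / (b - a + 1)
  }
  W
}

# Contract a weight matrix against spatial axis `axis` (2..4) of (C,D,H,W).
pool_axis4d <- function(x, W, axis) {
  perm <- append(setdiff(1:4, axis), axis, after = 0)
  xp <- aperm(x, perm)
  d <- dim(xp)
  m <- W %*% matrix(xp, d[1], prod(d[-1]))
  out <- array(m, dim = c(nrow(W), d[-1]))
  aperm(out, order(perm))
}

adaptive_avg_pool3d <- function(x, S) {
  d <- dim(x)
  for (ax in 2:4) {
    if (d[ax] != S) x <- pool_axis4d(x, adaptive_bins_matrix(dim(x)[ax], S), ax)
  }
  x
}

global_avg_pool <- function(x) rowMeans(matrix(x, dim(x)[1]))

# Inverted dropout; identity when training = FALSE or rate = 0.
dropout_tensor <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  keep <- stats::runif(length(x)) >= rate
  x * keep / (1 - rate)
}
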