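#' Preprocessing configuration
#'
#' Controls the deterministic MRI preprocessing chain: mask closing, brain
#' masking, z-score intensity normalization, and resampling to a cubic grid.
#'
#' @param target_side side length S of the output cube, in voxels (>= 4).
#'   Default 128, the input size the volumetric encoder expects at full scale.
#' @param closing_kernel side of the cubic structuring element used to close
#'   small holes in the brain mask before masking; one of 1 (no closing), 3, 5.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param min_brain_voxels minimum number of in-mask voxels for a mask to be
#'   considered usable.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_side = 128L, closing_kernel = 3L,
                              interpolation = c("trilinear", "nearest"),
                              min_brain_voxels = 32L) {
  interpolation <- match.arg(interpolation)
  assert_that(target_side >= 4, "target_side must be >= 4")
  assert_that(closing_kernel %in% c(1L, 3L, 5L),
              "closing_kernel must be one of 1, 3, 5")
  assert_that(min_brain_voxels >= 1, "min_brain_voxels must be positive")
  structure(list(target_side = as.integer(target_side),
                 closing_kernel = as.integer(closing_kernel),
                 interpolation = interpolation,
                 min_brain_voxels = as.integer(min_brain_voxels)),
            class = "preprocess_config")
}

# 1D grey/binary dilation (op = pmax) or erosion (op = pmin) along one axis by
# radius r, with `pad` as the out-of-volume value. A cubic structuring element
# separates into three 1D passes.
morph_1d <- function(a, axis, r, op, pad) {
  if (r == 0) return(a)
  d <- dim(a)
  out <- a
  for (o in seq_len(r)) {
    fwd <- array(pad, dim = d)
    bwd <- array(pad, dim = d)
    idx_src_f <- lapply(seq_along(d), function(k) {
      if (k == axis) seq_len(d[k] - o) + o else seq_len(d[k])
    })
    idx_dst_f <- lapply(seq_along(d), function(k) {
      if (k == axis) seq_len(d[k] - o) else seq_len(d[k])
    })
    fwd[idx_dst_f[[1]], idx_dst_f[[2]], idx_dst_f[[3]]] <-
      a[idx_src_f[[1]], idx_src_f[[2]], idx_src_f[[3]]]
    bwd[idx_src_f[[1]], idx_src_f[[2]], idx_src_f[[3]]] <-
      a[idx_dst_f[[1]], idx_dst_f[[2]], idx_dst_f[[3]]]
    out <- op(out, fwd, bwd)
  }
  out
}

morph_cube <- function(a, r, op, pad) {
  for (ax in 1:3) a <- morph_1d(a, ax, r, op, pad)
  a
}

#' Morphologically close a brain mask
#'
#' Binary closing (dilation then erosion) with a cubic structuring element,
#' used to smooth mask boundaries and fill pinholes before masking. Out-of-
#' volume voxels are treated as background for the dilation and as foreground
#' for the erosion, which makes closing idempotent at the borders.
#'
#' @param mask a [brain_mask].
#' @param kernel cubic kernel side, one of 1 (identity), 3, 5.
#' @return A closed [brain_mask].
#' @export
close_mask <- function(mask, kernel = 3L) {
  assert_that(kernel %in% c(1L, 3L, 5L), "closing kernel must be 1, 3 or 5")
  if (kernel == 1L) return(mask)
  r <- (kernel - 1L) %/% 2L
  d <- morph_cube(mask$data, r, pmax, pad = 0)
  e <- morph_cube(d, r, pmin, pad = 1)
  brain_mask(e)
}

#' Apply a brain mask to a volume (skull stripping)
#'
#' Computes the element-wise product of the intensity volume and its binary
#' brain mask, after morphological closing of the mask. Voxels outside the
#' brain become exactly 0.
#'
#' @param volume a [volume_image].
#' @param mask a [brain_mask] of the same shape.
#' @param cfg a [preprocess_config]; `closing_kernel` and `min_brain_voxels`
#'   are used.
#' @return The masked [volume_image]. The closed mask is attached as
#'   attribute `"closed_mask"`.
#' @export
apply_brain_mask <- function(volume, mask, cfg = preprocess_config()) {
  if (!identical(dim(volume$data), dim(mask$data))) {
    stop_gliofuse("volume and mask shapes differ", "gliofuse_dimension_error")
  }
  m <- close_mask(mask, cfg$closing_kernel)
  if (sum(m$data) < cfg$min_brain_voxels) {
    stop_gliofuse(sprintf("degenerate mask: %d brain voxels < required %d",
                          sum(m$data), cfg$min_brain_voxels),
                  "gliofuse_degenerate_mask_error")
  }
  out <- volume_image(volume$data * m$data, spacing = volume$spacing,
                      id = volume$id)
  attr(out, "closed_mask") <- m
  out
}

#' Z-score normalize a masked volume
#'
#' Standardizes intensities so the in-mask voxels have sample mean 0 and
#' sample standard deviation 1; out-of-mask voxels are set to 0. The mean and
#' standard deviation are computed over brain voxels only, so background zeros
#' do not bias the statistics.
#'
#' @param volume a [volume_image] (typically already masked).
#' @param mask the [brain_mask] defining the brain region.
#' @return The normalized [volume_image].
#' @export
zscore_normalize <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data))) {
    stop_gliofuse("volume and mask shapes differ", "gliofuse_dimension_error")
  }
  inside <- mask$data > 0
  vals <- volume$data[inside]
  assert_that(length(vals) >= 2, "need >= 2 brain voxels to normalize",
              "gliofuse_degenerate_mask_error")
  mu <- mean(vals)
  sigma <- stats::sd(vals)
  if (!is.finite(sigma) || sigma == 0) {
    stop_gliofuse("constant intensity within brain mask (sd = 0)",
                  "gliofuse_constant_volume_error")
  }
  out <- array(0, dim = dim(volume$data))
  out[inside] <- (vals - mu) / sigma
  volume_image(out, spacing = volume$spacing, id = volume$id)
}

# Interpolation weight matrix mapping n_in samples to n_out along one axis.
# Output coordinate i (0-based) maps to i*(n_in-1)/(n_out-1), so the endpoints
# coincide and an identity-size resize reproduces the input exactly.
interp_matrix <- function(n_in, n_out, mode) {
  coords <- if (n_out == 1) (n_in - 1) / 2 else
    (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  W <- matrix(0, n_out, n_in)
  if (mode == "nearest") {
    idx <- pmin(pmax(round(coords), 0), n_in - 1)
    W[cbind(seq_len(n_out), idx + 1)] <- 1
  } else {
    lo <- pmin(floor(coords), n_in - 1)
    w <- coords - lo
    hi <- pmin(lo + 1, n_in - 1)
    for (i in seq_len(n_out)) {
      W[i, lo[i] + 1] <- W[i, lo[i] + 1] + (1 - w[i])
      W[i, hi[i] + 1] <- W[i, hi[i] + 1] + w[i]
    }
  }
  W
}

# Contract weight matrix W (n_out x n_in) against axis `axis` of 3D array a.
apply_axis <- function(a, W, axis) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- W %*% matrix(ap, d[1], d[2] * d[3])
  out <- array(m, dim = c(nrow(W), d[2], d[3]))
  aperm(out, order(perm))
}

#' Resample a volume to a cubic grid
#'
#' Resizes the volume to `target_side^3` voxels by separable trilinear (or
#' nearest-neighbour) interpolation with endpoint-aligned sampling. An input
#' already at the target size is returned bitwise-identical; constant volumes
#' map to the same constant.
#'
#' @param volume a [volume_image].
#' @param cfg a [preprocess_config] (uses `target_side`, `interpolation`), or
#'   pass `side`/`interpolation` directly.
#' @param side optional override of the target side.
#' @param interpolation optional override of the interpolation mode.
#' @return The resampled [volume_image]; spacing is rescaled accordingly.
#' @export
resize_volume <- function(volume, cfg = preprocess_config(), side = NULL,
                          interpolation = NULL) {
  S <- as.integer(side %||% cfg$target_side)
  mode <- interpolation %||% cfg$interpolation
  assert_that(S >= 1, "target side must be positive")
  d <- dim(volume$data)
  a <- volume$data
  for (ax in 1:3) {
    if (d[ax] != S) a <- apply_axis(a, interp_matrix(d[ax], S, mode), ax)
  }
  new_spacing <- volume$spacing * d / S
  volume_image(a, spacing = new_spacing, id = volume$id)
}

# Otsu threshold of a numeric vector: maximizes between-class variance over a
# 256-bin histogram of the intensity range.
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  breaks[k + 1]
}

# Largest 6-connected foreground component by iterative min-label propagation.
largest_component <- function(fg) {
  d <- dim(fg)
  lab <- array(Inf, dim = d)
  lab[fg] <- seq_len(sum(fg))
  repeat {
    nb <- lab
    for (ax in 1:3) {
      for (o in c(-1L, 1L)) {
        shifted <- array(Inf, dim = d)
        src <- dst <- lapply(d, seq_len)
        n <- d[ax]
        if (o == 1L) { src[[ax]] <- 2:n; dst[[ax]] <- 1:(n - 1) }
        else { src[[ax]] <- 1:(n - 1); dst[[ax]] <- 2:n }
        shifted[dst[[1]], dst[[2]], dst[[3]]] <- lab[src[[1]], src[[2]], src[[3]]]
        nb <- pmin(nb, shifted)
      }
    }
    nb[!fg] <- Inf
    if (all(nb[fg] == lab[fg])) break
    lab <- nb
  }
  labs <- lab[fg]
  biggest <- as.numeric(names(which.max(table(labs))))
  out <- array(0, dim = d)
  out[fg][labs == biggest] <- 1
  out
}

#' Fallback brain-mask generator (Otsu + largest component)
#'
#' Deep-learning brain extraction is an external tool; for synthetic or toy
#' volumes this fallback thresholds intensities at the Otsu optimum and keeps
#' the largest 6-connected component as the brain.
#'
#' @param volume a [volume_image].
#' @param cfg a [preprocess_config]; `min_brain_voxels` is enforced.
#' @return A [brain_mask].
#' @export
otsu_brain_mask <- function(volume, cfg = preprocess_config()) {
  thr <- otsu_threshold(as.numeric(volume$data))
  fg <- volume$data > thr
  if (sum(fg) < cfg$min_brain_voxels) {
    stop_gliofuse("Otsu foreground below min_brain_voxels",
                  "gliofuse_degenerate_mask_error")
  }
  brain_mask(largest_component(fg))
}

#' Full MRI preprocessing chain
#'
#' Runs the complete deterministic chain: (optional fallback mask) -> mask
#' closing and skull stripping -> z-score normalization of brain voxels ->
#' resampling to a cubic grid.
#'
#' @param volume raw [volume_image].
#' @param mask optional [brain_mask]; when `NULL` an [otsu_brain_mask] is
#'   derived from the volume.
#' @param cfg a [preprocess_config].
#' @return The preprocessed [volume_image] of shape `target_side^3`.
#' @export
preprocess_volume <- function(volume, mask = NULL, cfg = preprocess_config()) {
  if (is.null(mask)) mask <- otsu_brain_mask(volume, cfg)
  stripped <- apply_brain_mask(volume, mask, cfg)
  normed <- zscore_normalize(stripped, attr(stripped, "closed_mask"))
  resize_volume(normed, cfg)
}
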