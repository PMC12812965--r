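#' Augmentation configuration
#'
#' Stochastic, label-preserving volume augmentations used during training:
#' small random rotations about a random axis, gamma contrast adjustment on
#' min-max-rescaled intensities, and a Gaussian-smoothed elastic deformation
#' field. All magnitudes at zero give the exact identity.
#'
#' @param rotation_max_deg maximum rotation magnitude in degrees (default 10).
#' @param contrast_gamma_range range of the gamma exponent
#'   (default `c(0.8, 1.2)`).
#' @param elastic_sigma Gaussian smoothing sd (voxels) of the displacement
#'   field (default 2).
#' @param elastic_alpha displacement amplitude in voxels (default 1; 0
#'   disables).
#' @param enabled_for_minority_boost whether minority classes receive extra
#'   augmented copies up to class balance during training.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotation_max_deg = 10, contrast_gamma_range = c(0.8, 1.2),
                           elastic_sigma = 2, elastic_alpha = 1,
                           enabled_for_minority_boost = TRUE) {
  assert_that(rotation_max_deg >= 0, "rotation_max_deg must be >= 0")
  assert_that(length(contrast_gamma_range) == 2 &&
                contrast_gamma_range[1] <= contrast_gamma_range[2] &&
                all(contrast_gamma_range > 0),
              "contrast_gamma_range must be an ordered positive pair")
  assert_that(elastic_sigma > 0 && elastic_alpha >= 0,
              "elastic parameters must be non-negative (sigma > 0)")
  structure(list(rotation_max_deg = rotation_max_deg,
                 contrast_gamma_range = as.numeric(contrast_gamma_range),
                 elastic_sigma = elastic_sigma, elastic_alpha = elastic_alpha,
                 enabled_for_minority_boost = isTRUE(enabled_for_minority_boost)),
            class = "augment_config")
}

# Trilinear sampling of a 3D array at arbitrary (possibly fractional) 1-based
# coordinates; out-of-volume samples return `fill`.
sample_trilinear <- function(a, coords, fill = 0) {
  d <- dim(a)
  out <- numeric(nrow(coords))
  # snap coordinates within rounding error of the volume bounds back inside
  snap <- function(v, n) {
    v[abs(v - 1) < 1e-8] <- 1
    v[abs(v - n) < 1e-8] <- n
    v
  }
  x <- snap(coords[, 1], d[1]); y <- snap(coords[, 2], d[2])
  z <- snap(coords[, 3], d[3])
  inb <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out[!inb] <- fill
  if (any(inb)) {
    x <- x[inb]; y <- y[inb]; z <- z[inb]
    x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
    z0 <- pmin(floor(z), d[3] - 1)
    x0 <- pmax(x0, 1); y0 <- pmax(y0, 1); z0 <- pmax(z0, 1)
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    idx <- function(i, j, k) (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i
    v <- (1 - fx) * (1 - fy) * (1 - fz) * a[idx(x0, y0, z0)] +
      fx * (1 - fy) * (1 - fz) * a[idx(x0 + 1, y0, z0)] +
      (1 - fx) * fy * (1 - fz) * a[idx(x0, y0 + 1, z0)] +
      fx * fy * (1 - fz) * a[idx(x0 + 1, y0 + 1, z0)] +
      (1 - fx) * (1 - fy) * fz * a[idx(x0, y0, z0 + 1)] +
      fx * (1 - fy) * fz * a[idx(x0 + 1, y0, z0 + 1)] +
      (1 - fx) * fy * fz * a[idx(x0, y0 + 1, z0 + 1)] +
      fx * fy * fz * a[idx(x0 + 1, y0 + 1, z0 + 1)]
    out[inb] <- v
  }
  out
}

# Rotate a volume by `deg` degrees about spatial axis `axis` (1..3) around
# the volume center, resampling trilinearly.
rotate_volume_array <- function(a, axis, deg) {
  if (deg == 0) return(a)
  d <- dim(a)
  th <- deg * pi / 180
  ctr <- (d + 1) / 2
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  rel <- sweep(g, 2, ctr)
  pl <- setdiff(1:3, axis)
  # inverse rotation of the target grid
  src <- rel
  src[, pl[1]] <- cos(th) * rel[, pl[1]] + sin(th) * rel[, pl[2]]
  src[, pl[2]] <- -sin(th) * rel[, pl[1]] + cos(th) * rel[, pl[2]]
  src <- sweep(src, 2, ctr, `+`)
  array(sample_trilinear(a, src), dim = d)
}

# Separable Gaussian smoothing of a 3D array (truncated at 3 sigma).
gaussian_smooth3d <- function(a, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(a)
  for (ax in 1:3) {
    perm <- append(setdiff(1:3, ax), ax, after = 0)
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, dp[1], dp[2] * dp[3])
    n <- dp[1]
    sm <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      rows <- pmin(pmax(seq_len(n) + o, 1), n)  # replicate-pad borders
      sm <- sm + k[o + r + 1] * m[rows, , drop = FALSE]
    }
    a <- aperm(array(sm, dp), order(perm))
  }
  a
}

#' Randomly augment a preprocessed volume
#'
#' Applies, in order: a rotation about one random axis with magnitude up to
#' `rotation_max_deg`; a gamma contrast adjustment of the min-max-rescaled
#' intensities; and an elastic deformation by a Gaussian-smoothed random
#' displacement field. Shape is preserved; the result is deterministic under
#' a fixed seed, and all-zero magnitudes return the input unchanged.
#'
#' @param volume a [volume_image].
#' @param cfg an [augment_config].
#' @param seed RNG seed for this draw.
#' @return The augmented [volume_image].
#' @export
augment_volume <- function(volume, cfg = augment_config(), seed = 1L) {
  with_seed(seed, {
    a <- volume$data
    d <- dim(a)
    if (cfg$rotation_max_deg > 0) {
      axis <- sample.int(3, 1)
      deg <- stats::runif(1, -cfg$rotation_max_deg, cfg$rotation_max_deg)
      a <- rotate_volume_array(a, axis, deg)
    }
    gr <- cfg$contrast_gamma_range
    if (!(gr[1] == 1 && gr[2] == 1)) {
      gamma <- stats::runif(1, gr[1], gr[2])
      lo <- min(a); hi <- max(a)
      if (hi > lo && gamma != 1) {
        a <- ((a - lo) / (hi - lo))^gamma * (hi - lo) + lo
      }
    }
    if (cfg$elastic_alpha > 0) {
      disp <- lapply(1:3, function(ax) {
        f <- array(stats::rnorm(prod(d)), dim = d)
        f <- gaussian_smooth3d(f, cfg$elastic_sigma)
        f / max(abs(f)) * cfg$elastic_alpha
      })
      g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                 z = seq_len(d[3])))
      src <- g
      for (ax in 1:3) src[, ax] <- src[, ax] + as.numeric(disp[[ax]])
      a <- array(sample_trilinear(a, src), dim = d)
    }
    volume_image(a, spacing = volume$spacing, id = volume$id)
  })
}
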