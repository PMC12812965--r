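#' Synthetic paired-cohort specification
#'
#' Describes a seeded synthetic cohort of paired MRI-like volumes and
#' expression profiles with planted, class-dependent, cross-modal signal. The
#' generator emulates the statistical structure a paired imaging-genomics
#' cohort provides — ellipsoidal "brain" volumes with class-shifted lesions,
#' and block-correlated expression with a class-shifted gene module — so the
#' whole pipeline is testable without any download.
#'
#' Two label rules exist. `"additive"` (default): both the lesion intensity/
#' radius and the designated gene-module mean shift with the class, so each
#' modality alone carries signal. `"interaction"` (requires 2 classes): the
#' label is the XOR of a lesion-laterality bit and a gene-module up/down bit,
#' so each modality alone is uninformative and only a cross-modal model can
#' recover the label.
#'
#' @param n_patients cohort size (default 60).
#' @param n_classes number of tumor classes (default 3).
#' @param class_proportions simplex vector (default `c(0.45, 0.35, 0.20)`,
#'   mildly imbalanced with the first class largest).
#' @param volume_side cubic volume side in voxels (default 16; minimum 8).
#' @param n_genes number of genes (default 50).
#' @param n_modules number of correlated gene modules (default 4).
#' @param effect_size class-shift magnitude planted in both modalities
#'   (default 2).
#' @param noise_sd intensity noise standard deviation (default 1).
#' @param label_rule `"additive"` or `"interaction"`.
#' @param seed master RNG seed.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_patients = 60L, n_classes = 3L,
                                  class_proportions = NULL, volume_side = 16L,
                                  n_genes = 50L, n_modules = 4L,
                                  effect_size = 2, noise_sd = 1,
                                  label_rule = c("additive", "interaction"),
                                  seed = 1L) {
  label_rule <- match.arg(label_rule)
  if (is.null(class_proportions)) {
    class_proportions <- if (n_classes == 3) c(0.45, 0.35, 0.20) else
      rep(1 / n_classes, n_classes)
  }
  assert_that(abs(sum(class_proportions) - 1) < 1e-8,
              "class proportions must sum to 1")
  assert_that(length(class_proportions) == n_classes,
              "one proportion per class required")
  assert_that(n_modules <= n_genes, "n_modules cannot exceed n_genes")
  assert_that(effect_size >= 0 && noise_sd > 0,
              "effect_size must be >= 0 and noise_sd > 0")
  if (label_rule == "interaction") {
    assert_that(n_classes == 2,
                "the interaction label rule is defined for 2 classes")
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_classes = as.integer(n_classes),
                 class_proportions = as.numeric(class_proportions),
                 volume_side = as.integer(volume_side),
                 n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 effect_size = effect_size, noise_sd = noise_sd,
                 label_rule = label_rule, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# Ellipsoid indicator on a cubic grid: center cx (voxels), semi-axes r.
ellipsoid_mask <- function(side, cx, r) {
  ax <- seq_len(side)
  dx <- outer((ax - cx[1])^2 / r[1]^2, rep(1, side)) # side x side (x,y)
  dy <- outer(rep(1, side), (ax - cx[2])^2 / r[2]^2)
  plane <- dx + dy
  out <- array(0, dim = c(side, side, side))
  for (z in ax) out[, , z] <- (plane + (z - cx[3])^2 / r[3]^2 <= 1) * 1
  out
}

#' Generate one synthetic MRI-like volume with its brain mask
#'
#' Gaussian background noise inside an ellipsoidal brain; one ellipsoidal
#' lesion whose mean added intensity (`1 + effect_size * (class_id - 1)`) and
#' radius grow with the class index, so at `effect_size = 0` the classes are
#' statistically identical.
#'
#' @param class_id class label in `1..n_classes`.
#' @param spec a [synthetic_cohort_spec].
#' @param seed RNG seed for this draw.
#' @param lesion_side optional lateralization `"left"`/`"right"` (used by the
#'   interaction label rule); `NULL` places the lesion at a random offset.
#' @return A list with `volume` ([volume_image]) and `mask` ([brain_mask]);
#'   the lesion indicator is attached to the volume as attribute `"lesion"`.
#' @export
generate_volume <- function(class_id, spec, seed = spec$seed,
                            lesion_side = NULL) {
  assert_that(spec$volume_side >= 8, "volume_side must be >= 8",
              "gliofuse_size_error")
  assert_that(class_id >= 1 && class_id <= spec$n_classes,
              "class_id out of range", "gliofuse_value_error")
  s <- spec$volume_side
  with_seed(seed, {
    ctr <- (s + 1) / 2
    brain <- ellipsoid_mask(s, c(ctr, ctr, ctr),
                            s * c(0.44, 0.40, 0.36))
    vol <- array(0, dim = c(s, s, s))
    inside <- brain > 0
    vol[inside] <- stats::rnorm(sum(inside), mean = 0, sd = spec$noise_sd)
    # lesion geometry: radius and intensity shift with the class index under
    # the additive rule; under the interaction rule the lesion appearance is
    # class-independent and only its laterality carries the image bit
    # under the interaction rule the lesion is salient (brightness scales
    # with effect_size) but identical across classes; only laterality varies
    cshift <- if (spec$label_rule == "interaction") 0 else class_id - 1
    base_mu <- if (spec$label_rule == "interaction") 1 + spec$effect_size else 1
    r_les <- s * 0.11 * (1 + 0.08 * spec$effect_size * cshift)
    cx <- if (is.null(lesion_side)) {
      ctr + stats::runif(3, -0.12 * s, 0.12 * s)
    } else {
      xc <- if (lesion_side == "left") 0.33 * s else 0.67 * s
      c(xc, ctr + stats::runif(1, -0.08 * s, 0.08 * s),
        ctr + stats::runif(1, -0.08 * s, 0.08 * s))
    }
    lesion <- ellipsoid_mask(s, cx, rep(r_les, 3)) * brain
    les_in <- lesion > 0
    mu <- base_mu + spec$effect_size * cshift
    vol[les_in] <- vol[les_in] +
      stats::rnorm(sum(les_in), mean = mu, sd = spec$noise_sd / 2)
    v <- volume_image(vol, spacing = c(1, 1, 1), id = "synthetic")
    attr(v, "lesion") <- les_in
    list(volume = v, mask = brain_mask(brain))
  })
}

# Module sizes by largest remainder so every generator call agrees.
module_sizes <- function(spec) {
  largest_remainder(spec$n_genes, rep(1 / spec$n_modules, spec$n_modules))
}

#' Generate one synthetic expression profile
#'
#' Genes are partitioned into `n_modules` blocks; a per-block latent factor
#' induces within-block correlation (factor loading `sqrt(0.6)`, so pairwise
#' expected correlation 0.6). The first block is the designated signal
#' module: under the additive rule its mean shifts by
#' `effect_size * (class_id - 1)`; under the interaction rule it shifts by
#' `module_dir * effect_size / 2`, with the direction balanced across
#' patients so the marginal carries no class signal. Values are exponentiated
#' (`2^(x + 5)`) so the marginals are log-normal-like and strictly positive.
#'
#' @param class_id class label in `1..n_classes`.
#' @param spec a [synthetic_cohort_spec].
#' @param seed RNG seed for this draw.
#' @param patient_id identifier for the resulting profile.
#' @param module_dir +1 or -1 direction of the signal-module shift
#'   (interaction rule only).
#' @return An [expression_profile] with genes `gene_001 ...`.
#' @export
generate_expression <- function(class_id, spec, seed = spec$seed,
                                patient_id = "synthetic", module_dir = NULL) {
  assert_that(class_id >= 1 && class_id <= spec$n_classes,
              "class_id out of range", "gliofuse_value_error")
  sizes <- module_sizes(spec)
  rho <- 0.6
  with_seed(seed, {
    x <- numeric(spec$n_genes)
    pos <- 0L
    for (b in seq_along(sizes)) {
      nb <- sizes[b]
      if (nb == 0) next
      f <- stats::rnorm(1)
      eps <- stats::rnorm(nb)
      xb <- sqrt(rho) * f + sqrt(1 - rho) * eps
      if (b == 1) {
        shift <- if (spec$label_rule == "interaction" && !is.null(module_dir)) {
          module_dir * spec$effect_size / 2
        } else {
          spec$effect_size * (class_id - 1)
        }
        xb <- xb + shift
      }
      x[pos + seq_len(nb)] <- xb
      pos <- pos + nb
    }
    vals <- 2^(x + 5)
    names(vals) <- sprintf("gene_%03d", seq_len(spec$n_genes))
    expression_profile(vals, patient_id)
  })
}

#' Generate a full paired synthetic cohort on disk
#'
#' Allocates class labels by largest-remainder rounding of the class
#' proportions, draws a paired volume + mask + expression profile for every
#' patient (both modalities always present), and writes NIfTI volumes and
#' masks, a genes x patients expression TSV (byte-identical under the same
#' seed), and a pairing manifest CSV with columns `patient_id`, `image_path`,
#' `mask_path`, `label`.
#'
#' @param spec a [synthetic_cohort_spec].
#' @param dir output directory (created if needed).
#' @return The manifest data.frame, invisibly; also written to
#'   `<dir>/manifest.csv`.
#' @export
generate_cohort <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- largest_remainder(spec$n_patients, spec$class_proportions)
  labels <- rep(seq_len(spec$n_classes), counts)
  labels <- with_seed(derive_seed(spec$seed, "label-order"),
                      sample(labels, length(labels)))
  ids <- sprintf("P%04d", seq_len(spec$n_patients))
  profiles <- vector("list", spec$n_patients)
  manifest <- data.frame(patient_id = ids, image_path = "", mask_path = "",
                         label = labels, stringsAsFactors = FALSE)
  for (i in seq_len(spec$n_patients)) {
    lesion_side <- NULL
    module_dir <- NULL
    if (spec$label_rule == "interaction") {
      sbit <- with_seed(derive_seed(spec$seed, paste0("side-", i)),
                        stats::rbinom(1, 1, 0.5))
      gbit <- bitwXor(sbit, labels[i] - 1L)
      lesion_side <- if (sbit == 1) "right" else "left"
      module_dir <- if (gbit == 1) 1 else -1
    }
    vm <- generate_volume(labels[i], spec,
                          seed = derive_seed(spec$seed, paste0("vol-", i)),
                          lesion_side = lesion_side)
    vm$volume$id <- ids[i]
    img_path <- file.path(dir, sprintf("%s_vol.nii.gz", ids[i]))
    msk_path <- file.path(dir, sprintf("%s_mask.nii.gz", ids[i]))
    write_nifti_volume(vm$volume, img_path)
    write_nifti_volume(vm$mask, msk_path)
    manifest$image_path[i] <- img_path
    manifest$mask_path[i] <- msk_path
    profiles[[i]] <- generate_expression(
      labels[i], spec, seed = derive_seed(spec$seed, paste0("expr-", i)),
      patient_id = ids[i], module_dir = module_dir)
  }
  write_expression_table(profiles, file.path(dir, "expression.tsv"))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
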