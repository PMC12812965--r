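test_that("volume generation is seeded and plants the class signal", {
  spec <- synthetic_cohort_spec(n_patients = 10, volume_side = 12,
                                effect_size = 2, seed = 5)
  # same seed twice: identical volumes
  a <- generate_volume(1, spec, seed = 99)
  b <- generate_volume(1, spec, seed = 99)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_true(all(a$mask$data %in% c(0, 1)))

  expect_error(generate_volume(5, spec), class = "gliofuse_value_error")
  expect_error(
    generate_volume(1, synthetic_cohort_spec(volume_side = 6)),
    class = "gliofuse_size_error")
})

test_that("lesion mean intensity difference tracks the effect size", {
  spec <- synthetic_cohort_spec(volume_side = 12, effect_size = 2,
                                noise_sd = 1, seed = 2)
  mc_mean <- function(class_id, n = 200) {
    mean(vapply(seq_len(n), function(i) {
      vm <- generate_volume(class_id, spec, seed = 1000 * class_id + i)
      mean(vm$volume$data[attr(vm$volume, "lesion")])
    }, numeric(1)))
  }
  d21 <- mc_mean(2) - mc_mean(1)
  expect_equal(d21, spec$effect_size, tolerance = 0.15)

  # zero effect: classes are statistically identical
  spec0 <- synthetic_cohort_spec(volume_side = 12, effect_size = 0, seed = 2)
  m1 <- mean(vapply(1:100, function(i) {
    vm <- generate_volume(1, spec0, seed = i)
    mean(vm$volume$data[attr(vm$volume, "lesion")])
  }, numeric(1)))
  m3 <- mean(vapply(1:100, function(i) {
    vm <- generate_volume(3, spec0, seed = 50000 + i)
    mean(vm$volume$data[attr(vm$volume, "lesion")])
  }, numeric(1)))
  expect_equal(m1, m3, tolerance = 0.15)
})

test_that("expression modules are correlated within and shifted by class", {
  spec <- synthetic_cohort_spec(n_genes = 40, n_modules = 4,
                                effect_size = 2, seed = 9)
  # same seed: identical profile
  p1 <- generate_expression(1, spec, seed = 7)
  p2 <- generate_expression(1, spec, seed = 7)
  expect_identical(p1$values, p2$values)
  expect_true(all(p1$values > 0))

  # within-block correlation beats between-block at n = 200
  n <- 200
  mat <- vapply(seq_len(n), function(i)
    log2(generate_expression(1, spec, seed = i)$values + 1),
    numeric(spec$n_genes))
  cm <- cor(t(mat))
  sizes <- gliofuse:::module_sizes(spec)
  block <- rep(seq_along(sizes), sizes)
  within <- mean(cm[outer(block, block, "==") & upper.tri(cm)])
  between <- mean(cm[outer(block, block, "!=") & upper.tri(cm)])
  expect_gt(within, between + 0.3)

  # class shift concentrates on the designated module
  mat3 <- vapply(seq_len(n), function(i)
    log2(generate_expression(3, spec, seed = 10000 + i)$values + 1),
    numeric(spec$n_genes))
  shift <- rowMeans(mat3) - rowMeans(mat)
  expect_equal(mean(shift[block == 1]), 2 * spec$effect_size,
               tolerance = 0.2)
  expect_equal(mean(shift[block != 1]), 0, tolerance = 0.15)
})

test_that("cohorts are allocated by largest remainder and reproducible", {
  expect_equal(gliofuse:::largest_remainder(12, c(0.5, 0.25, 0.25)),
               c(6L, 3L, 3L))
  expect_equal(gliofuse:::largest_remainder(7, c(0.5, 0.3, 0.2)),
               c(4L, 2L, 1L))

  dir1 <- file.path(tempdir(), "syn1"); dir2 <- file.path(tempdir(), "syn2")
  spec <- synthetic_cohort_spec(n_patients = 12,
                                class_proportions = c(0.5, 0.25, 0.25),
                                volume_side = 8, n_genes = 12, n_modules = 3,
                                seed = 3)
  man <- generate_cohort(spec, dir1)
  expect_equal(nrow(man), 12)
  expect_equal(unname(table(man$label)), c(6L, 3L, 3L), ignore_attr = TRUE)
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$mask_path)))

  # same seed: byte-identical expression table
  generate_cohort(spec, dir2)
  expect_identical(readBin(file.path(dir1, "expression.tsv"), "raw", 1e6),
                   readBin(file.path(dir2, "expression.tsv"), "raw", 1e6))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("interaction cohorts hide the label from each single modality", {
  spec <- synthetic_cohort_spec(n_patients = 40, n_classes = 2,
                                class_proportions = c(0.5, 0.5),
                                volume_side = 12, effect_size = 3,
                                label_rule = "interaction", seed = 13)
  dir <- file.path(tempdir(), "syn_int")
  man <- generate_cohort(spec, dir)
  # lesion intensity and size are class-independent under the XOR rule
  les_mean <- function(rows) {
    mean(vapply(rows, function(i) {
      v <- read_nifti_volume(man$image_path[i])
      mean(v$data[v$data > 2])       # salient lesion voxels
    }, numeric(1)))
  }
  m1 <- les_mean(which(man$label == 1))
  m2 <- les_mean(which(man$label == 2))
  expect_equal(m1, m2, tolerance = 0.25)
  unlink(dir, recursive = TRUE)
})
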