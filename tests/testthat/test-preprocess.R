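test_that("brain masking multiplies element-wise and closes the mask first", {
  v <- volume_image(array(rnorm(4^3), dim = c(4, 4, 4)), id = "a")
  cfg1 <- preprocess_config(target_side = 4, closing_kernel = 1,
                            min_brain_voxels = 1)

  # all-ones mask, kernel 1: identity
  out <- apply_brain_mask(v, brain_mask(cube(4, 1)), cfg1)
  expect_identical(out$data, v$data)

  # all-zeros mask: degenerate
  expect_error(apply_brain_mask(v, brain_mask(cube(4, 0)), cfg1),
               class = "gliofuse_degenerate_mask_error")

  # single interior voxel: elementwise oracle over all 64 voxels
  v2 <- volume_image(cube(4, 2.0))
  m <- cube(4, 0); m[2, 3, 2] <- 1
  out2 <- apply_brain_mask(v2, brain_mask(m), cfg1)
  oracle <- array(0, dim = c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    oracle[i, j, k] <- v2$data[i, j, k] * m[i, j, k]
  }
  expect_equal(out2$data, oracle)
  expect_equal(sum(out2$data), 2.0)

  # shape mismatch
  expect_error(apply_brain_mask(v, brain_mask(cube(5, 1)), cfg1),
               class = "gliofuse_dimension_error")
})

test_that("masking with a closed mask is idempotent", {
  set.seed(4)
  v <- volume_image(array(rnorm(8^3), dim = c(8, 8, 8)))
  m <- brain_mask((array(runif(8^3), dim = c(8, 8, 8)) > 0.4) * 1)
  cfg <- preprocess_config(target_side = 8, closing_kernel = 3,
                           min_brain_voxels = 1)
  once <- apply_brain_mask(v, m, cfg)
  closed <- attr(once, "closed_mask")
  twice <- apply_brain_mask(once, closed, cfg)
  expect_identical(twice$data, once$data)
  # closing itself is idempotent
  expect_identical(close_mask(closed, 3)$data, closed$data)
})

test_that("z-score normalization standardizes brain voxels and zeros the rest", {
  # two brain voxels {1, 3}: symmetric around 0
  v <- volume_image(cube(4, 0)); v$data[1, 1, 1] <- 1; v$data[2, 1, 1] <- 3
  m <- cube(4, 0); m[1, 1, 1] <- m[2, 1, 1] <- 1
  out <- zscore_normalize(v, brain_mask(m))
  expect_equal(out$data[1, 1, 1], -out$data[2, 1, 1])
  expect_equal(out$data[1, 1, 1] + out$data[2, 1, 1], 0)
  expect_equal(sum(out$data[m == 0]), 0)

  # constant brain region: sd = 0 error
  vc <- volume_image(cube(4, 7))
  expect_error(zscore_normalize(vc, brain_mask(cube(4, 1))),
               class = "gliofuse_constant_volume_error")

  # {0,1,2,3,4}: hand-computed mean/sd oracle
  v5 <- volume_image(cube(6, 0))
  m5 <- cube(6, 0)
  for (i in 1:5) { v5$data[i, 2, 2] <- i - 1; m5[i, 2, 2] <- 1 }
  # include the zero-valued voxel in the mask; v5[1,2,2] = 0 anyway
  m5[1, 2, 2] <- 1
  out5 <- zscore_normalize(v5, brain_mask(m5))
  sd5 <- sqrt(sum((0:4 - 2)^2) / 4)            # sample sd of {0..4}
  expect_equal(out5$data[5, 2, 2], (4 - 2) / sd5)
  vals <- out5$data[m5 == 1]
  expect_equal(mean(vals), 0, tolerance = 1e-6)
  expect_equal(sd(vals), 1, tolerance = 1e-6)
})

test_that("z-score normalization is idempotent on the same mask", {
  set.seed(9)
  v <- volume_image(array(rnorm(6^3, 10, 4), dim = c(6, 6, 6)))
  m <- brain_mask((array(runif(6^3), dim = c(6, 6, 6)) > 0.3) * 1)
  once <- zscore_normalize(v, m)
  twice <- zscore_normalize(once, m)
  expect_equal(twice$data, once$data, tolerance = 1e-10)
})

test_that("volume resizing honors identity, constants and linear ramps", {
  cfg <- preprocess_config(target_side = 6, min_brain_voxels = 1)
  v <- volume_image(array(rnorm(6^3), dim = c(6, 6, 6)))
  expect_identical(resize_volume(v, cfg)$data, v$data)   # bitwise identity

  vc <- volume_image(array(7.5, dim = c(5, 9, 3)))
  out <- resize_volume(vc, cfg)
  expect_equal(dim(out$data), c(6, 6, 6))
  expect_equal(as.numeric(out$data), rep(7.5, 6^3))

  # 1D ramp downsampled by 2: values from an independent linear interpolator
  ramp <- volume_image(array(rep(0:7, 16), dim = c(8, 4, 4)))
  half <- resize_volume(ramp, side = 4, interpolation = "trilinear")
  expected <- approx(x = 0:7, y = 0:7, xout = (0:3) * 7 / 3)$y
  expect_equal(half$data[, 1, 1], expected)
  # monotone ramp keeps its global min/max ordering
  expect_equal(which.min(half$data[, 2, 2]), 1)
  expect_equal(which.max(half$data[, 2, 2]), 4)
})

test_that("expression log-normalization follows log2(x + 1)", {
  p <- expression_profile(c(a = 0, b = 1, c = 255), "P1")
  out <- log_normalize_expression(p)
  expect_equal(unname(out$values), c(0, 1, 8))
  pneg <- expression_profile(c(a = 5, b = 2), "P2")
  pneg$values["b"] <- -1
  expect_error(log_normalize_expression(pneg), class = "gliofuse_value_error")
})

test_that("QC filtering drops unreliable genes and imputes the rest", {
  m <- matrix(c(1, 2, 3, 4,
                5, 5, 5, 5,
                2, NA, 4, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), paste0("P", 1:4)))
  profs <- profiles_from_matrix(m)

  # no missing values, min_variance 0: unchanged gene set
  clean <- qc_filter(profiles_from_matrix(m[1:2, , drop = FALSE]),
                     max_missing_frac = 0, min_variance = 0)
  expect_equal(names(clean[[1]]$values), c("gA", "gB"))

  # gene missing everywhere: dropped
  m2 <- m; m2["gC", ] <- NA
  out2 <- qc_filter(profiles_from_matrix(m2), max_missing_frac = 0.2,
                    min_variance = 0)
  expect_false("gC" %in% names(out2[[1]]$values))

  # brute-force oracle on the 3 x 4 toy with stated thresholds
  max_miss <- 0.3; min_var <- 0.5
  keep_oracle <- vapply(rownames(m), function(g) {
    x <- m[g, ]
    mean(is.na(x)) <= max_miss && var(x[!is.na(x)]) >= min_var
  }, logical(1))
  out3 <- qc_filter(profs, max_missing_frac = max_miss, min_variance = min_var)
  expect_setequal(names(out3[[1]]$values), rownames(m)[keep_oracle])
  # imputation by gene-wise median
  expect_equal(out3[[2]]$values[["gC"]], median(c(2, 4, 6)))

  expect_error(qc_filter(profs, max_missing_frac = 0, min_variance = 1e9),
               class = "gliofuse_empty_panel_error")
})

test_that("co-expression graph matches an all-pairs correlation oracle", {
  # two perfectly correlated genes
  m <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("P", 1:4)))
  g <- build_gene_graph(profiles_from_matrix(m), corr_threshold = 0.9)
  expect_equal(nrow(g$edges), 1)

  # a gene and its negation: |r| = 1 still one edge
  m2 <- rbind(g1 = c(1, 2, 3, 4), g2 = -c(1, 2, 3, 4))
  colnames(m2) <- paste0("P", 1:4)
  g2 <- build_gene_graph(profiles_from_matrix(m2), corr_threshold = 0.9)
  expect_equal(nrow(g2$edges), 1)

  # 5-gene toy vs exhaustive pairwise Pearson oracle
  set.seed(11)
  m5 <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(sprintf("g%d", 1:5),
                                                   paste0("P", 1:8)))
  m5[2, ] <- m5[1, ] + rnorm(8, sd = 0.1)
  g5 <- build_gene_graph(profiles_from_matrix(m5), corr_threshold = 0.7)
  oracle <- NULL
  for (i in 1:4) for (j in (i + 1):5) {
    if (abs(cor(m5[i, ], m5[j, ])) >= 0.7) oracle <- rbind(oracle, c(i, j))
  }
  expect_equal(unname(as.matrix(g5$edges)), unname(oracle))
})

test_that("co-expression graph is invariant to patient and gene order", {
  set.seed(12)
  m <- matrix(rnorm(6 * 10), 6, 10, dimnames = list(sprintf("g%d", 1:6),
                                                    paste0("P", 1:10)))
  m[4, ] <- 0.9 * m[3, ] + rnorm(10, sd = 0.2)
  base <- build_gene_graph(profiles_from_matrix(m), corr_threshold = 0.6)

  pperm <- sample(10)
  gp <- build_gene_graph(profiles_from_matrix(m[, pperm]), corr_threshold = 0.6)
  expect_equal(gp$edges, base$edges)

  gperm <- sample(6)
  gg <- build_gene_graph(profiles_from_matrix(m[gperm, ]), corr_threshold = 0.6)
  # relabel back to the original indexing
  remap <- match(gg$nodes, base$nodes)
  e <- t(apply(matrix(remap[gg$edges], ncol = 2), 1, sort))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  expect_equal(unname(e), unname(as.matrix(base$edges)))
})

test_that("edge-list mode dedupes and rejects unknown symbols", {
  profs <- profiles_from_matrix(
    matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), paste0("P", 1:4))))
  el <- rbind(c("a", "b"), c("b", "a"), c("a", "c"))
  g <- build_gene_graph(profs, edge_source = "edge_list", edge_list = el)
  expect_equal(nrow(g$edges), 2)
  expect_error(
    build_gene_graph(profs, edge_source = "edge_list",
                     edge_list = rbind(c("a", "zz"))),
    class = "gliofuse_key_error")
})

test_that("Otsu fallback mask recovers a bright ellipsoid", {
  set.seed(5)
  s <- 16
  brain <- gliofuse:::ellipsoid_mask(s, rep(8.5, 3), c(6, 5, 5))
  v <- array(rnorm(s^3, 0, 0.1), dim = rep(s, 3)) + brain * 10
  mask <- otsu_brain_mask(volume_image(v),
                          preprocess_config(min_brain_voxels = 10))
  agreement <- mean(mask$data == brain)
  expect_gt(agreement, 0.98)
})
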