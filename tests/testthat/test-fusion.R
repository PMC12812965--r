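make_block <- function(C = 4, Fg = 3, seed = 9) {
  init_fusion_block(fusion_config(shared_dim = 4, attn_hidden = 3,
                                  cross_attn_dim = 2, seed = seed),
                    mri_channels = C, gene_dim = Fg,
                    mri_vec_dim = 4, gene_vec_dim = 4)
}

test_that("cross-modal attention normalizes over genes at every cell", {
  set.seed(20)
  fm <- feature_map3d(array(rnorm(4 * 2^3), dim = c(4, 2, 2, 2)), "p")
  G <- matrix(rnorm(3 * 3), 3, 3)
  out <- cross_modal_graph_attention(fm, G, make_block())
  beta <- attr(out, "beta")
  expect_equal(dim(beta), c(8, 3))
  expect_equal(rowSums(beta), rep(1, 8), tolerance = 1e-6)
  expect_true(all(beta >= 0))

  # single gene: beta = 1 everywhere
  out1 <- cross_modal_graph_attention(fm, G[1, , drop = FALSE], make_block())
  expect_equal(as.numeric(attr(out1, "beta")), rep(1, 8))

  # zero attention vector: uniform 1/N
  blk <- make_block()
  blk$a[] <- 0
  outu <- cross_modal_graph_attention(fm, G, blk)
  expect_equal(as.numeric(attr(outu, "beta")), rep(1 / 3, 24))

  # no genes: error
  expect_error(cross_modal_graph_attention(fm, G[0, , drop = FALSE],
                                           make_block()),
               class = "gliofuse_empty_graph_error")
})

test_that("cross-modal attention matches a per-cell enumeration oracle", {
  set.seed(21)
  C <- 4; N <- 3; Fg <- 3
  fm <- feature_map3d(array(rnorm(C * 8), dim = c(C, 2, 2, 2)), "p")
  G <- matrix(rnorm(N * Fg), N, Fg)
  blk <- make_block(C, Fg, seed = 33)
  out <- cross_modal_graph_attention(fm, G, blk)
  lrelu <- function(x) ifelse(x >= 0, x, 0.2 * x)
  dp <- length(blk$a) / 2
  oracle <- fm$tensor
  for (d in 1:2) for (h in 1:2) for (w in 1:2) {
    cell <- fm$tensor[, d, h, w]
    q <- blk$W_query %*% cell
    logits <- sapply(1:N, function(i) {
      k <- blk$W_key %*% G[i, ]
      lrelu(sum(blk$a * c(q, k)))
    })
    beta <- exp(logits - max(logits)); beta <- beta / sum(beta)
    msg <- rep(0, C)
    for (i in 1:N) msg <- msg + beta[i] * (blk$W_msg %*% G[i, ])
    oracle[, d, h, w] <- cell + msg
  }
  expect_equal(out$tensor, oracle, tolerance = 1e-10)
})

test_that("residual attention with a zero message projection is the identity", {
  set.seed(22)
  fm <- feature_map3d(array(rnorm(4 * 8), dim = c(4, 2, 2, 2)), "p")
  blk <- make_block()
  blk$W_msg[] <- 0
  out <- cross_modal_graph_attention(fm, matrix(rnorm(9), 3, 3), blk)
  expect_equal(out$tensor, fm$tensor)
})

test_that("the attended message is invariant to gene permutation", {
  set.seed(23)
  fm <- feature_map3d(array(rnorm(4 * 8), dim = c(4, 2, 2, 2)), "p")
  G <- matrix(rnorm(5 * 3), 5, 3)
  blk <- make_block(4, 3)
  base <- cross_modal_graph_attention(fm, G, blk)
  perm <- sample(5)
  permuted <- cross_modal_graph_attention(fm, G[perm, ], blk)
  expect_equal(permuted$tensor, base$tensor, tolerance = 1e-10)
})

test_that("latent projection is the declared affine map", {
  blk <- make_block()
  # identity W, zero b returns inputs unchanged
  blk$W_mri <- diag(4); blk$b_mri <- rep(0, 4)
  blk$W_gen <- matrix(0, 4, 4); blk$b_gen <- rep(2, 4)
  z <- project_to_latent(c(1, 2, 3, 4), c(9, 9, 9, 9), blk)
  expect_equal(z$z_mri, c(1, 2, 3, 4))
  expect_equal(z$z_gene, rep(2, 4))                  # zero W, b = c

  # random case vs explicit matrix-vector loop
  set.seed(24)
  blk$W_mri <- matrix(rnorm(16), 4, 4); blk$b_mri <- rnorm(4)
  x <- rnorm(4)
  zz <- project_to_latent(x, rep(0, 4), blk)
  oracle <- sapply(1:4, function(i) sum(blk$W_mri[i, ] * x) + blk$b_mri[i])
  expect_equal(zz$z_mri, oracle)

  expect_error(project_to_latent(c(1, 2), c(1, 2, 3, 4), blk),
               class = "gliofuse_shape_error")
})

test_that("modality attention is a two-way softmax of the scores", {
  blk <- make_block()
  z <- rnorm(4)
  w_same <- modality_attention(z, z, blk)
  expect_equal(unname(w_same), c(0.5, 0.5))           # symmetric inputs
  expect_equal(sum(w_same), 1)

  # engineered scores: e_mri = 1, e_gene = 0 -> (e/(e+1), 1/(e+1))
  blk1 <- make_block()
  blk1$W_a <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0), 3, 4)
  blk1$v <- c(2, 0, 0)
  z1 <- c(atanh(0.5), 0, 0, 0)                        # tanh -> 0.5, e = 1
  z0 <- rep(0, 4)                                     # e = 0
  w <- modality_attention(z1, z0, blk1)
  expect_equal(unname(w), c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)

  # saturation: a huge score gap drives the weights to (1, 0)
  blk1$v <- c(1e4, 0, 0)
  wsat <- modality_attention(z1, z0, blk1)
  expect_equal(unname(wsat), c(1, 0), tolerance = 1e-10)
})

test_that("fusion is the recorded convex combination", {
  z1 <- c(1, -2, 3); z2 <- c(4, 0, -1)
  f10 <- fuse(z1, z2, c(1, 0))
  expect_equal(f10$vector, z1)

  fmix <- fuse(z1, z2, c(0.25, 0.75))
  expect_equal(fmix$vector, 0.25 * z1 + 0.75 * z2)
  expect_equal(unname(fmix$modality_weights), c(0.25, 0.75))

  # convexity fixed point and per-coordinate bounds
  v <- rnorm(3)
  expect_equal(fuse(v, v, c(0.3, 0.7))$vector, v)
  expect_true(all(fmix$vector >= pmin(z1, z2) - 1e-12 &
                    fmix$vector <= pmax(z1, z2) + 1e-12))

  expect_error(fuse(z1, z2, c(0.5, 0.6)), class = "gliofuse_contract_error")
  expect_error(fuse(z1, z2[1:2], c(0.5, 0.5)), class = "gliofuse_shape_error")
})

test_that("the fusion report writes one JSON line per patient", {
  set.seed(25)
  betas <- list(matrix(runif(8 * 3), 8, 3))
  betas[[1]] <- betas[[1]] / rowSums(betas[[1]])
  path <- tempfile(fileext = ".jsonl")
  write_fusion_report("P1", list(c(mri = 0.4, genomic = 0.6)), betas,
                      c("gA", "gB", "gC"), path, top_m = 2)
  lines <- readLines(path)
  expect_length(lines, 1)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$alpha_genomic, 0.6)
  expect_length(rec$top_genes, 2)
  unlink(path)
})
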