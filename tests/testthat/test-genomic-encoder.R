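test_that("attention weights are a softmax over each neighborhood", {
  # randomized instances: weights non-negative, summing to 1 per node
  for (s in 1:5) {
    set.seed(s)
    n <- 6
    edges <- cbind(sample(n, 4, TRUE), sample(n, 4, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    g <- gene_graph(sprintf("g%d", 1:n), edges)
    H <- matrix(rnorm(n * 3), n, 3)
    W <- matrix(rnorm(2 * 3), 2, 3)
    a <- rnorm(4)
    co <- gat_attention_coefficients(g, H, W, a)
    for (i in 1:n) {
      expect_true(all(co$alpha[[i]] >= 0))
      expect_equal(sum(co$alpha[[i]]), 1, tolerance = 1e-6)
    }
  }
})

test_that("equal-logit neighborhoods get uniform attention", {
  # star graph, every node carries the same feature vector
  g <- gene_graph(sprintf("g%d", 1:5), cbind(1, 2:5))
  H <- matrix(1, 5, 2)
  co <- gat_attention_coefficients(g, H, matrix(rnorm(4), 2, 2), rnorm(4))
  expect_equal(co$alpha[[1]], rep(1 / 5, 5))          # hub + 4 spokes + self

  # single node with a self-loop
  g1 <- gene_graph("g1", NULL)
  co1 <- gat_attention_coefficients(g1, matrix(2, 1, 1),
                                    matrix(1, 1, 1), c(1, 1))
  expect_equal(co1$alpha[[1]], 1)

  # isolated node without self-loops is undefined
  expect_error(
    gat_attention_coefficients(g1, matrix(2, 1, 1), matrix(1, 1, 1),
                               c(1, 1), add_self_loops = FALSE),
    class = "gliofuse_undefined_neighborhood_error")
})

test_that("attention matches brute-force enumeration on a path graph", {
  g <- gene_graph(c("a", "b", "c", "d"), cbind(1:3, 2:4))
  H <- matrix(c(0.5, -1, 2, 0.3, 1, 0, -0.5, 0.7), 4, 2)
  W <- matrix(c(1, 0.5, -0.3, 0.2), 2, 2)
  a <- c(0.4, -0.2, 0.1, 0.3)
  slope <- 0.2
  co <- gat_attention_coefficients(g, H, W, a, leaky_slope = slope)
  # independent evaluation: explicit loops over every neighbor pair
  lrelu <- function(x) ifelse(x >= 0, x, slope * x)
  proj <- H %*% t(W)
  nb <- list(c(1, 2), c(1, 2, 3), c(2, 3, 4), c(3, 4))
  for (i in 1:4) {
    logits <- sapply(nb[[i]], function(j)
      lrelu(sum(a * c(proj[i, ], proj[j, ]))))
    expect_equal(co$alpha[[i]], exp(logits) / sum(exp(logits)),
                 tolerance = 1e-10)
  }
})

test_that("a GAT layer agrees with a dense double-loop oracle", {
  g <- toy_graph(n_genes = 5, np = 2, edges = cbind(c(1, 2, 3, 1), c(2, 3, 4, 5)))
  enc <- init_gat_encoder(gat_config(heads_layer1 = 2, heads_layer2 = 1,
                                     hidden_dim = 3, out_dim = 4, seed = 8),
                          in_dim = 1)
  H <- matrix(g$expression[, 1], ncol = 1)
  got <- gat_layer_forward(g, H, enc, 1L)
  # oracle: per head, explicit neighborhood softmax + weighted sum, concat,
  # ELU
  lrelu <- function(x) ifelse(x >= 0, x, 0.2 * x)
  elu_ref <- function(x) ifelse(x >= 0, x, exp(x) - 1)
  nb <- list(c(1, 2, 5), c(1, 2, 3), c(2, 3, 4), c(3, 4), c(1, 5))
  heads <- lapply(enc$layer1, function(h) {
    p <- H %*% t(h$W)
    out <- matrix(0, 5, 3)
    for (i in 1:5) {
      lg <- sapply(nb[[i]], function(j)
        lrelu(sum(h$a * c(p[i, ], p[j, ]))))
      al <- exp(lg - max(lg)); al <- al / sum(al)
      for (k in seq_along(nb[[i]])) out[i, ] <- out[i, ] + al[k] * p[nb[[i]][k], ]
    }
    out
  })
  oracle <- elu_ref(do.call(cbind, heads))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("GAT outputs are node-permutation equivariant", {
  set.seed(31)
  g <- toy_graph(n_genes = 6, np = 2)
  enc <- init_gat_encoder(tiny_gat_config(seed = 2), in_dim = 1)
  base <- encode_genome(g, "P1", enc)
  perm <- sample(6)
  gp <- gene_graph(g$nodes[perm],
                   matrix(match(matrix(g$nodes[as.matrix(g$edges)], ncol = 2),
                                g$nodes[perm]), ncol = 2),
                   expression = g$expression[perm, , drop = FALSE])
  permuted <- encode_genome(gp, "P1", enc)
  expect_equal(permuted$node_matrix, base$node_matrix[perm, ],
               tolerance = 1e-10)
  # pooled embedding is permutation invariant
  expect_equal(permuted$embedding, base$embedding, tolerance = 1e-10)
})

test_that("genome encoding hits the configured dimension and pooling rules", {
  set.seed(15)
  genes <- sprintf("gene_%03d", 1:50)
  expr <- matrix(abs(rnorm(50 * 4, 5, 1)), 50, 4,
                 dimnames = list(genes, paste0("P", 1:4)))
  edges <- cbind(sample(50, 40, TRUE), sample(50, 40, TRUE))
  edges <- edges[edges[, 1] != edges[, 2], ]
  g <- gene_graph(genes, edges, expression = expr)

  out <- encode_genome(g, "P1", init_gat_encoder(gat_config(seed = 1)))
  expect_length(out$embedding, 256)                  # default output width

  enc <- init_gat_encoder(tiny_gat_config(), in_dim = 1)
  g6 <- toy_graph(n_genes = 6, np = 2)
  mean_out <- encode_genome(g6, "P1", enc, pooling = "mean")
  expect_equal(mean_out$embedding, colMeans(mean_out$node_matrix))
  # single-node graph: pooled vector equals the node embedding
  g1 <- gene_graph("solo", NULL,
                   expression = matrix(2, 1, 1,
                                       dimnames = list("solo", "P1")))
  one <- encode_genome(g1, "P1", enc, pooling = "mean")
  expect_equal(one$embedding, as.numeric(one$node_matrix))
  # two eval passes agree bitwise
  expect_identical(encode_genome(g6, "P1", enc)$node_matrix,
                   encode_genome(g6, "P1", enc)$node_matrix)
})

test_that("node embeddings export to a TSV with one row per gene", {
  g <- toy_graph(n_genes = 4, np = 1, edges = cbind(1:3, 2:4))
  enc <- init_gat_encoder(tiny_gat_config(), in_dim = 1)
  out <- encode_genome(g, "P1", enc)
  path <- tempfile(fileext = ".tsv")
  export_node_embeddings(out$node_matrix, g$nodes, path)
  df <- read.delim(path)
  expect_equal(nrow(df), 4)
  expect_equal(ncol(df), 1 + ncol(out$node_matrix))
  unlink(path)
})
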