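# Shared fixtures, built in code at test time.

cube <- function(side, value = 0) array(value, dim = rep(side, 3))

# Named expression profiles from a genes x patients matrix.
profiles_from_matrix <- function(m) {
  lapply(seq_len(ncol(m)), function(j) {
    expression_profile(stats::setNames(m[, j], rownames(m)),
                       colnames(m)[j] %||% paste0("P", j))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small volume with a bright blob centered at `ctr` (vector of 3).
blob_volume <- function(side, ctr, radius = 3, amplitude = 5, seed = 1) {
  set.seed(seed)
  a <- array(rnorm(side^3, sd = 0.1), dim = rep(side, 3))
  idx <- as.matrix(expand.grid(x = 1:side, y = 1:side, z = 1:side))
  d2 <- rowSums(sweep(idx, 2, ctr)^2)
  a[d2 <= radius^2] <- a[d2 <= radius^2] + amplitude
  volume_image(a, id = "blob")
}

# Tiny deterministic gene graph with expression for `np` patients.
toy_graph <- function(n_genes = 6, np = 4, edges = cbind(1:5, 2:6), seed = 3) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  expr <- matrix(rnorm(n_genes * np), n_genes, np,
                 dimnames = list(genes, paste0("P", seq_len(np))))
  gene_graph(genes, edges, expression = expr)
}

# Independent reference softmax for oracle computations.
ref_softmax <- function(z) exp(z - max(z)) / sum(exp(z - max(z)))
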