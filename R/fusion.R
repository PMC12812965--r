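#' Fusion configuration
#'
#' Parameters for the two fusion mechanisms: (1) spatial cross-modal graph
#' attention, where every spatial cell of the MRI feature map attends over the
#' gene-node embeddings and absorbs a projected genomic message (optionally as
#' a residual update); (2) adaptive modality-attention fusion, where the
#' pooled per-modality vectors are projected into a shared d-dimensional
#' latent space and convexly combined with learned two-way softmax weights.
#'
#' @param shared_dim shared latent dimension d (default 256).
#' @param attn_hidden modality-attention hidden width h (default 128).
#' @param cross_attn_dim common attention dimension d' of the cross-modal
#'   logits (default 128).
#' @param residual add the attended genomic message to the MRI cell features
#'   (TRUE, default) instead of replacing them.
#' @param seed RNG seed for parameter initialization.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(shared_dim = 256L, attn_hidden = 128L,
                          cross_attn_dim = 128L, residual = TRUE,
                          seed = 42L) {
  assert_that(shared_dim >= 1 && attn_hidden >= 1 && cross_attn_dim >= 1,
              "all fusion dimensions must be >= 1")
  structure(list(shared_dim = as.integer(shared_dim),
                 attn_hidden = as.integer(attn_hidden),
                 cross_attn_dim = as.integer(cross_attn_dim),
                 residual = isTRUE(residual), seed = as.integer(seed)),
            class = "fusion_config")
}

#' Fused patient embedding
#'
#' The convex combination of the projected modality vectors together with the
#' modality weights that produced it (the model's interpretability surface).
#'
#' @param vector length-d numeric vector.
#' @param modality_weights named numeric pair `c(mri = ..., genomic = ...)`
#'   that is non-negative and sums to 1.
#' @return An object of class `fused_embedding`.
#' @export
fused_embedding <- function(vector, modality_weights) {
  assert_that(length(modality_weights) == 2 && all(modality_weights >= 0) &&
                abs(sum(modality_weights) - 1) <= 1e-6,
              "modality weights must be non-negative and sum to 1",
              "gliofuse_contract_error")
  structure(list(vector = as.numeric(vector),
                 modality_weights = stats::setNames(as.numeric(modality_weights),
                                                    c("mri", "genomic"))),
            class = "fused_embedding")
}

#' @export
print.fused_embedding <- function(x, ...) {
  cat(sprintf("<fused_embedding> d=%d  alpha_mri=%.3f alpha_genomic=%.3f\n",
              length(x$vector), x$modality_weights[1], x$modality_weights[2]))
  invisible(x)
}

#' Initialize the fusion parameters
#'
#' Creates the learnable parameter store: the cross-modal projections
#' (`W_query` d' x C over MRI cell features, `W_key` d' x F over gene
#' embeddings, attention vector `a` of length 2d', message projection `W_msg`
#' C x F), the latent projections (`W_mri`, `b_mri`, `W_gen`, `b_gen`) and the
#' modality-attention parameters (`W_a` h x d, `v` length h).
#'
#' @param cfg a [fusion_config].
#' @param mri_channels channel count C of the MRI feature map.
#' @param gene_dim embedding dimension F of the gene nodes.
#' @param mri_vec_dim length of the pooled MRI vector entering Z_mri.
#' @param gene_vec_dim length of the pooled genomic vector entering Z_gen.
#' @return An object of class `fusion_block`.
#' @export
init_fusion_block <- function(cfg = fusion_config(), mri_channels,
                              gene_dim, mri_vec_dim = mri_channels,
                              gene_vec_dim = gene_dim) {
  with_seed(cfg$seed, {
    structure(list(
      cfg = cfg,
      W_query = xavier_uniform(cfg$cross_attn_dim, mri_channels),
      W_key = xavier_uniform(cfg$cross_attn_dim, gene_dim),
      a = stats::runif(2 * cfg$cross_attn_dim,
                       -sqrt(3 / cfg$cross_attn_dim),
                       sqrt(3 / cfg$cross_attn_dim)),
      W_msg = xavier_uniform(mri_channels, gene_dim),
      W_mri = xavier_uniform(cfg$shared_dim, mri_vec_dim),
      b_mri = rep(0, cfg$shared_dim),
      W_gen = xavier_uniform(cfg$shared_dim, gene_vec_dim),
      b_gen = rep(0, cfg$shared_dim),
      W_a = xavier_uniform(cfg$attn_hidden, cfg$shared_dim),
      v = stats::runif(cfg$attn_hidden, -sqrt(3 / cfg$attn_hidden),
                       sqrt(3 / cfg$attn_hidden))
    ), class = "fusion_block")
  })
}

#' Spatial cross-modal graph attention
#'
#' For every spatial cell s of the MRI feature map, computes attention logits
#' against every gene node from the LeakyReLU of the concatenated projections
#' of the cell feature (query) and the gene embedding (key), normalizes them
#' with a softmax over genes (so the weights at each cell sum to 1), and adds
#' the attended, channel-projected genomic message to the cell's feature
#' vector (residual mode) or replaces it.
#'
#' @param mri_map a [feature_map3d] with C channels.
#' @param gene_nodes N x F node-embedding matrix (from [encode_genome]).
#' @param block a [init_fusion_block] parameter store.
#' @param leaky_slope LeakyReLU negative slope for the attention logits.
#' @return A [feature_map3d] of identical shape; the per-cell attention
#'   matrix (cells x genes) is attached as attribute `"beta"`.
#' @export
cross_modal_graph_attention <- function(mri_map, gene_nodes, block,
                                        leaky_slope = 0.2) {
  N <- nrow(gene_nodes)
  if (is.null(N) || N == 0) {
    stop_gliofuse("no gene nodes to attend over", "gliofuse_empty_graph_error")
  }
  x <- mri_map$tensor
  d <- dim(x)
  C <- d[1]
  assert_that(ncol(block$W_query) == C && ncol(block$W_key) == ncol(gene_nodes),
              "fusion block shapes do not match inputs",
              "gliofuse_shape_error")
  ncell <- prod(d[2:4])
  Xc <- matrix(x, C, ncell)                      # C x cells
  dp <- length(block$a) / 2
  q <- block$W_query %*% Xc                      # d' x cells
  kmat <- block$W_key %*% t(gene_nodes)          # d' x N
  a1 <- block$a[seq_len(dp)]
  a2 <- block$a[dp + seq_len(dp)]
  sq <- as.numeric(crossprod(q, a1))             # cells
  sk <- as.numeric(crossprod(kmat, a2))          # N
  logits <- leaky_relu(outer(sq, sk, `+`), leaky_slope)  # cells x N
  beta <- softmax_rows(logits)
  msg_nodes <- block$W_msg %*% t(gene_nodes)     # C x N
  msg <- msg_nodes %*% t(beta)                   # C x cells
  out <- if (block$cfg$residual) Xc + msg else msg
  fm <- feature_map3d(array(out, dim = d), mri_map$patient_id)
  attr(fm, "beta") <- beta
  fm
}

#' Project modality vectors into the shared latent space
#'
#' Affine maps `Z = W x + b` taking the pooled MRI vector and the pooled
#' genomic vector into the common d-dimensional space where they can be
#' compared and combined.
#'
#' @param mri_vec pooled MRI feature vector.
#' @param gene_vec pooled genomic embedding vector.
#' @param block a [init_fusion_block].
#' @return A list with `z_mri` and `z_gene`, both length `shared_dim`.
#' @export
project_to_latent <- function(mri_vec, gene_vec, block) {
  assert_that(length(mri_vec) == ncol(block$W_mri),
              sprintf("MRI vector length %d does not match projection (%d)",
                      length(mri_vec), ncol(block$W_mri)),
              "gliofuse_shape_error")
  assert_that(length(gene_vec) == ncol(block$W_gen),
              sprintf("genomic vector length %d does not match projection (%d)",
                      length(gene_vec), ncol(block$W_gen)),
              "gliofuse_shape_error")
  list(z_mri = as.numeric(block$W_mri %*% mri_vec + block$b_mri),
       z_gene = as.numeric(block$W_gen %*% gene_vec + block$b_gen))
}

#' Adaptive modality attention weights
#'
#' Scores each projected modality vector with `e = v^T tanh(W_a z)` and
#' normalizes the two scores with a softmax, yielding non-negative weights
#' that sum to 1. (The printed form of the two-way normalization in the
#' source model description repeats the MRI score in both numerators; the
#' standard softmax — each weight using its own score — is implemented.)
#'
#' @param z_mri,z_gene length-d projected modality vectors.
#' @param block a [init_fusion_block].
#' @return Named numeric pair `c(mri = alpha_mri, genomic = alpha_genomic)`.
#' @export
modality_attention <- function(z_mri, z_gene, block) {
  e_mri <- sum(block$v * tanh(block$W_a %*% z_mri))
  e_gen <- sum(block$v * tanh(block$W_a %*% z_gene))
  w <- softmax_vec(c(e_mri, e_gen))
  stats::setNames(w, c("mri", "genomic"))
}

#' Fuse the modality vectors
#'
#' Convex combination `F_fused = alpha_mri * Z_mri + alpha_genomic * Z_gene`;
#' the weights are recorded on the result for interpretability reporting.
#'
#' @param z_mri,z_gene length-d projected modality vectors.
#' @param weights numeric pair of non-negative weights summing to 1 (e.g. from
#'   [modality_attention]).
#' @return A [fused_embedding].
#' @export
fuse <- function(z_mri, z_gene, weights) {
  assert_that(length(z_mri) == length(z_gene),
              "modality vectors differ in length", "gliofuse_shape_error")
  if (abs(sum(weights) - 1) > 1e-6 || any(weights < 0)) {
    stop_gliofuse("fusion weights must be non-negative and sum to 1",
                  "gliofuse_contract_error")
  }
  fused_embedding(weights[1] * z_mri + weights[2] * z_gene, weights)
}

#' Write a per-patient fusion interpretability report (JSON lines)
#'
#' One JSON object per patient: the modality weights and the top-m genes
#' ranked by spatially averaged cross-modal attention.
#'
#' @param patient_ids character vector.
#' @param modality_weights list of named weight pairs per patient.
#' @param betas list of cells x genes attention matrices per patient.
#' @param genes gene symbols (column order of the betas).
#' @param path output path.
#' @param top_m how many genes to report (default 10).
#' @return `path` invisibly.
#' @export
write_fusion_report <- function(patient_ids, modality_weights, betas, genes,
                                path, top_m = 10L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(patient_ids)) {
    mean_beta <- colMeans(betas[[i]])
    ord <- order(-mean_beta)[seq_len(min(top_m, length(genes)))]
    rec <- list(patient_id = patient_ids[i],
                alpha_mri = unname(modality_weights[[i]][1]),
                alpha_genomic = unname(modality_weights[[i]][2]),
                top_genes = genes[ord],
                top_gene_attention = unname(mean_beta[ord]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 8), con)
  }
  invisible(path)
}
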