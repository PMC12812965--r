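#' Graph attention encoder configuration
#'
#' A two-layer graph attention network over the gene-interaction graph. The
#' first layer runs `heads_layer1` attention heads of width `hidden_dim` and
#' concatenates them (ELU nonlinearity); the second layer maps to the final
#' `out_dim`-dimensional node embeddings (heads averaged if more than one,
#' identity output activation). Attention logits use a LeakyReLU with slope
#' `leaky_slope`; self-loops guarantee every node a non-empty neighborhood.
#'
#' @param heads_layer1 attention heads in layer 1 (default 8).
#' @param heads_layer2 attention heads in layer 2 (default 1).
#' @param hidden_dim per-head width of layer 1 (default 32, so 8 heads
#'   concatenate to 256 entering layer 2).
#' @param out_dim node-embedding dimension (default 256).
#' @param dropout dropout rate on attention coefficients and intermediate
#'   features during training (default 0.3; inactive in eval mode).
#' @param leaky_slope negative slope of the attention LeakyReLU (default 0.2).
#' @param add_self_loops add a self-loop to every node before attention.
#' @param seed RNG seed for Xavier-uniform weight initialization.
#' @return An object of class `gat_config`.
#' @export
gat_config <- function(heads_layer1 = 8L, heads_layer2 = 1L, hidden_dim = 32L,
                       out_dim = 256L, dropout = 0.3, leaky_slope = 0.2,
                       add_self_loops = TRUE, seed = 42L) {
  assert_that(heads_layer1 >= 1 && heads_layer2 >= 1 && hidden_dim >= 1 &&
                out_dim >= 1, "all GAT dimensions must be positive")
  structure(list(heads_layer1 = as.integer(heads_layer1),
                 heads_layer2 = as.integer(heads_layer2),
                 hidden_dim = as.integer(hidden_dim),
                 out_dim = as.integer(out_dim), dropout = dropout,
                 leaky_slope = leaky_slope,
                 add_self_loops = isTRUE(add_self_loops),
                 seed = as.integer(seed)),
            class = "gat_config")
}

#' Desk-scale GAT preset
#'
#' 4 heads of width 8 concatenating to 32, matching the tiny volumetric
#' preset's 32-channel output.
#'
#' @param seed RNG seed.
#' @return A [gat_config].
#' @export
tiny_gat_config <- function(seed = 42L) {
  gat_config(heads_layer1 = 4L, heads_layer2 = 1L, hidden_dim = 8L,
             out_dim = 32L, seed = seed)
}

#' Initialize the genomic encoder
#'
#' @param cfg a [gat_config].
#' @param in_dim input node-feature dimension (default 1: one normalized
#'   expression scalar per gene, projected up by the first layer).
#' @return An object of class `gat_encoder`.
#' @export
init_gat_encoder <- function(cfg = gat_config(), in_dim = 1L) {
  with_seed(cfg$seed, {
    layer1 <- lapply(seq_len(cfg$heads_layer1), function(h) {
      list(W = xavier_uniform(cfg$hidden_dim, in_dim),
           a = stats::runif(2 * cfg$hidden_dim, -sqrt(6 / (2 * cfg$hidden_dim + 1)),
                            sqrt(6 / (2 * cfg$hidden_dim + 1))))
    })
    d1 <- cfg$hidden_dim * cfg$heads_layer1
    layer2 <- lapply(seq_len(cfg$heads_layer2), function(h) {
      list(W = xavier_uniform(cfg$out_dim, d1),
           a = stats::runif(2 * cfg$out_dim, -sqrt(6 / (2 * cfg$out_dim + 1)),
                            sqrt(6 / (2 * cfg$out_dim + 1))))
    })
    structure(list(cfg = cfg, in_dim = as.integer(in_dim),
                   layer1 = layer1, layer2 = layer2),
              class = "gat_encoder")
  })
}

#' Attention coefficients of one GAT head
#'
#' For every node i and neighbor j, computes the softmax-normalized attention
#' weight from the logit `LeakyReLU(a^T [W h_i || W h_j])`, so within every
#' neighborhood the weights are non-negative and sum to 1.
#'
#' @param graph a [gene_graph].
#' @param embeddings N x F numeric matrix of node features.
#' @param W F' x F projection matrix.
#' @param a length-2F' attention vector.
#' @param leaky_slope LeakyReLU negative slope.
#' @param add_self_loops include each node in its own neighborhood.
#' @return A list with `neighbors` (list of neighbor index vectors per node)
#'   and `alpha` (list of matching weight vectors).
#' @export
gat_attention_coefficients <- function(graph, embeddings, W, a,
                                       leaky_slope = 0.2,
                                       add_self_loops = TRUE) {
  n <- length(graph$nodes)
  assert_that(n >= 1, "empty graph", "gliofuse_empty_graph_error")
  assert_that(nrow(embeddings) == n, "embeddings do not match graph",
              "gliofuse_dimension_error")
  fp <- nrow(W)
  assert_that(ncol(W) == ncol(embeddings) && length(a) == 2 * fp,
              "projection/attention shapes inconsistent",
              "gliofuse_shape_error")
  g <- embeddings %*% t(W)                 # N x F'
  s_src <- as.numeric(g %*% a[seq_len(fp)])
  s_dst <- as.numeric(g %*% a[fp + seq_len(fp)])
  nb <- neighbor_list(graph, add_self_loops)
  alpha <- vector("list", n)
  for (i in seq_len(n)) {
    js <- nb[[i]]
    if (length(js) == 0) {
      stop_gliofuse(sprintf(
        "node %d has no neighbors and self-loops are disabled", i),
        "gliofuse_undefined_neighborhood_error")
    }
    logits <- leaky_relu(s_src[i] + s_dst[js], leaky_slope)
    alpha[[i]] <- softmax_vec(logits)
  }
  list(neighbors = nb, alpha = alpha, projected = g)
}

# One attention head: returns the N x F' aggregated messages.
gat_head_fwd <- function(graph, embeddings, head, leaky_slope,
                         add_self_loops, dropout = 0, training = FALSE) {
  co <- gat_attention_coefficients(graph, embeddings, head$W, head$a,
                                   leaky_slope, add_self_loops)
  g <- co$projected
  n <- nrow(g)
  out <- matrix(0, n, ncol(g))
  for (i in seq_len(n)) {
    w <- co$alpha[[i]]
    if (training && dropout > 0) {
      keep <- stats::runif(length(w)) >= dropout
      w <- w * keep / (1 - dropout)
    }
    out[i, ] <- crossprod(g[co$neighbors[[i]], , drop = FALSE], w)
  }
  out
}

#' Forward pass through one GAT layer
#'
#' Layer 1 concatenates its heads and applies an ELU; layer 2 averages its
#' heads and applies no output nonlinearity (the pooled embedding feeds the
#' fusion module directly). Deterministic in eval mode.
#'
#' @param graph a [gene_graph].
#' @param embeddings N x F input node features.
#' @param encoder a [init_gat_encoder] model.
#' @param layer_index 1 or 2.
#' @param training logical; enables attention/feature dropout.
#' @return N x d numeric matrix of updated node embeddings.
#' @export
gat_layer_forward <- function(graph, embeddings, encoder, layer_index,
                              training = FALSE) {
  cfg <- encoder$cfg
  heads <- if (layer_index == 1) encoder$layer1 else encoder$layer2
  outs <- lapply(heads, function(h)
    gat_head_fwd(graph, embeddings, h, cfg$leaky_slope, cfg$add_self_loops,
                 cfg$dropout, training))
  if (layer_index == 1) {
    h <- do.call(cbind, outs)
    h <- elu(h)
    if (training && cfg$dropout > 0) {
      keep <- matrix(stats::runif(length(h)) >= cfg$dropout, nrow(h))
      h <- h * keep / (1 - cfg$dropout)
    }
    h
  } else {
    Reduce(`+`, outs) / length(outs)
  }
}

#' Encode a patient's expression graph into an embedding
#'
#' Runs both GAT layers over the gene graph using the patient's normalized
#' expression as the initial one-dimensional node features, then pools the
#' node embeddings into a single patient-level vector.
#'
#' @param graph a [gene_graph] carrying a cohort expression matrix.
#' @param patient_id which patient's expression column to use; alternatively
#'   pass `features` directly.
#' @param encoder a [init_gat_encoder] model.
#' @param pooling `"mean"` or `"max"` over nodes.
#' @param features optional explicit N x in_dim feature matrix.
#' @param training logical; enables dropout.
#' @return A list with `embedding` (length `out_dim`) and `node_matrix`
#'   (N x `out_dim`, for the cross-modal attention layer).
#' @export
encode_genome <- function(graph, patient_id = NULL, encoder = init_gat_encoder(),
                          pooling = c("mean", "max"), features = NULL,
                          training = FALSE) {
  pooling <- match.arg(pooling)
  assert_that(length(graph$nodes) >= 1, "empty gene graph",
              "gliofuse_empty_graph_error")
  if (is.null(features)) features <- node_features_for(graph, patient_id)
  h <- gat_layer_forward(graph, features, encoder, 1L, training)
  h <- gat_layer_forward(graph, h, encoder, 2L, training)
  emb <- if (pooling == "mean") colMeans(h) else apply(h, 2, max)
  list(embedding = emb, node_matrix = h)
}

#' Export node embeddings to TSV
#'
#' @param node_matrix N x d embedding matrix (from [encode_genome]).
#' @param genes character vector of gene symbols (row order).
#' @param path output path.
#' @return `path` invisibly.
#' @export
export_node_embeddings <- function(node_matrix, genes, path) {
  df <- data.frame(gene = genes, node_matrix, check.names = FALSE)
  names(df) <- c("gene", paste0("dim_", seq_len(ncol(node_matrix)) - 1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
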