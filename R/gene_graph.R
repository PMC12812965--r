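#' Gene-interaction graph
#'
#' An undirected graph whose nodes are genes and whose edges encode putative
#' biological interactions — either curated (edge list) or statistical
#' (co-expression). The per-patient node features consumed by the graph
#' encoder are the normalized expression values (one scalar per gene), stored
#' here as a genes x patients matrix.
#'
#' @param nodes character vector of gene symbols (node order).
#' @param edges integer matrix with 2 columns of 1-based node indices; stored
#'   canonically with `edges[,1] < edges[,2]`, deduplicated, no self-loops.
#' @param expression optional genes x patients matrix of normalized expression
#'   (rows aligned with `nodes`).
#' @return An object of class `gene_graph`.
#' @export
gene_graph <- function(nodes, edges, expression = NULL) {
  nodes <- as.character(nodes)
  assert_that(!anyDuplicated(nodes), "duplicate gene symbols in node list",
              "gliofuse_value_error")
  n <- length(nodes)
  if (length(edges) == 0) {
    edges <- matrix(integer(0), ncol = 2)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2)
    assert_that(all(edges >= 1 & edges <= n), "edge endpoint out of range",
                "gliofuse_value_error")
    edges <- t(apply(edges, 1, sort))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  if (!is.null(expression)) {
    assert_that(nrow(expression) == n,
                "expression rows must match node count",
                "gliofuse_dimension_error")
    rownames(expression) <- nodes
  }
  structure(list(nodes = nodes, edges = edges, expression = expression),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("<gene_graph> %d genes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (is.null(x$expression)) "" else
                sprintf(", expression for %d patients", ncol(x$expression))))
  invisible(x)
}

#' Build a gene-interaction graph from a cohort
#'
#' In `"correlation"` mode an undirected edge connects genes i and j whenever
#' the absolute Pearson correlation of their expression across patients is at
#' least `corr_threshold` (signed co-expression counts as interaction). A
#' zero-variance gene simply receives no correlation edges. In `"edge_list"`
#' mode the supplied gene-symbol pairs are used verbatim after deduplication.
#'
#' @param profiles list of [expression_profile] objects (typically already
#'   log-normalized and QC-filtered) sharing a gene index.
#' @param edge_source `"correlation"` or `"edge_list"`.
#' @param corr_threshold absolute-correlation cutoff (default 0.7).
#' @param edge_list two-column character matrix/data.frame of gene symbols
#'   (required in `"edge_list"` mode).
#' @return A [gene_graph] carrying the cohort expression matrix.
#' @export
build_gene_graph <- function(profiles,
                             edge_source = c("correlation", "edge_list"),
                             corr_threshold = 0.7, edge_list = NULL) {
  edge_source <- match.arg(edge_source)
  m <- profiles_to_matrix(profiles)
  assert_that(!anyNA(m), "run qc_filter before building the graph",
              "gliofuse_value_error")
  genes <- rownames(m)
  if (edge_source == "correlation") {
    assert_that(ncol(m) >= 2,
                "correlation mode needs >= 2 patients",
                "gliofuse_value_error")
    cm <- suppressWarnings(stats::cor(t(m)))  # zero-variance genes give NA
    cm[is.na(cm)] <- 0
    hits <- which(abs(cm) >= corr_threshold & upper.tri(cm), arr.ind = TRUE)
    edges <- matrix(as.integer(hits), ncol = 2)
  } else {
    assert_that(!is.null(edge_list), "edge_list mode requires an edge list")
    el <- as.matrix(edge_list)[, 1:2, drop = FALSE]
    idx <- matrix(match(el, genes), ncol = 2)
    if (anyNA(idx)) {
      bad <- unique(el[is.na(idx)])
      stop_gliofuse(sprintf("unknown gene symbol(s) in edge list: %s",
                            paste(bad, collapse = ", ")),
                    "gliofuse_key_error")
    }
    edges <- idx
  }
  gene_graph(genes, edges, expression = m)
}

#' Read a two-column undirected edge list (TSV of gene symbols)
#'
#' @param path path to a tab-separated file with two columns of gene symbols
#'   (no header, or a header that is skipped if it matches `gene`/`from`).
#' @return A two-column character matrix.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) > 0 && tolower(df[1, 1]) %in% c("gene", "gene1", "from")) {
    df <- df[-1, , drop = FALSE]
  }
  as.matrix(df[, 1:2, drop = FALSE])
}

# Per-patient node feature matrix (N x 1): the gene's normalized expression.
node_features_for <- function(graph, patient_id) {
  assert_that(!is.null(graph$expression), "graph carries no expression matrix")
  assert_that(patient_id %in% colnames(graph$expression),
              sprintf("unknown patient '%s'", patient_id),
              "gliofuse_key_error")
  matrix(graph$expression[, patient_id], ncol = 1,
         dimnames = list(graph$nodes, "expr"))
}

# Neighbor index list with optional self-loops, shared by the GAT layers.
neighbor_list <- function(graph, add_self_loops = TRUE) {
  n <- length(graph$nodes)
  nb <- vector("list", n)
  if (add_self_loops) for (i in seq_len(n)) nb[[i]] <- i
  if (nrow(graph$edges) > 0) {
    for (r in seq_len(nrow(graph$edges))) {
      i <- graph$edges[r, 1]; j <- graph$edges[r, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  lapply(nb, function(v) sort(unique(v)))
}
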