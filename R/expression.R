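#' Per-patient gene expression profile
#'
#' @param values named numeric vector of non-negative expression values,
#'   indexed by gene symbol. `NA` marks a missing measurement (removed or
#'   imputed by [qc_filter()]); non-missing values must be finite.
#' @param patient_id patient identifier string.
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(values, patient_id) {
  assert_that(is.numeric(values) && !is.null(names(values)) &&
                all(nzchar(names(values))),
              "values must be a named numeric vector", "gliofuse_value_error")
  assert_that(!anyDuplicated(names(values)),
              "duplicate gene symbols in expression profile",
              "gliofuse_value_error")
  assert_that(all(is.finite(values) | is.na(values)),
              "expression values must be finite or NA", "gliofuse_value_error")
  structure(list(values = values, patient_id = as.character(patient_id)),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s  %d genes  %d missing\n",
              x$patient_id, length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Log-transform an expression profile
#'
#' Applies the standard `log2(x + 1)` transform to stabilize the heavy right
#' tail of expression counts; 0 maps to 0 and the transform is monotone.
#'
#' @param profile an [expression_profile] with non-negative values.
#' @return The transformed [expression_profile].
#' @export
log_normalize_expression <- function(profile) {
  v <- profile$values
  if (any(v < 0, na.rm = TRUE)) {
    stop_gliofuse("negative expression values cannot be log-normalized",
                  "gliofuse_value_error")
  }
  out <- profile
  out$values <- log2(v + 1)
  out
}

# Stack a list of profiles sharing a gene index into a genes x patients matrix.
profiles_to_matrix <- function(profiles) {
  assert_that(length(profiles) >= 1, "need at least one profile")
  genes <- names(profiles[[1]]$values)
  for (p in profiles) {
    assert_that(identical(names(p$values), genes),
                "profiles do not share a common gene index",
                "gliofuse_value_error")
  }
  m <- vapply(profiles, function(p) unname(p$values), numeric(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, vapply(profiles, `[[`, "", "patient_id")))
  m
}

matrix_to_profiles <- function(m) {
  lapply(colnames(m), function(pid) {
    expression_profile(stats::setNames(m[, pid], rownames(m)), pid)
  })
}

#' Quality-control filter for a cohort of expression profiles
#'
#' Drops genes that are unreliable across the cohort and imputes the rest:
#' a gene is removed from all profiles if its fraction of missing values
#' exceeds `max_missing_frac` or its cross-patient variance (computed on the
#' observed values) falls below `min_variance`. Remaining missing values are
#' imputed with the gene-wise median.
#'
#' @param profiles list of [expression_profile] objects sharing a gene index.
#' @param max_missing_frac maximum tolerated fraction of missing values per
#'   gene (default 0.2).
#' @param min_variance minimum cross-patient variance per gene (default 1e-8,
#'   i.e. drop only genes that are numerically constant).
#' @return The filtered and imputed list of profiles, with attribute
#'   `"dropped_genes"` naming the removed genes.
#' @export
qc_filter <- function(profiles, max_missing_frac = 0.2, min_variance = 1e-8) {
  m <- profiles_to_matrix(profiles)
  miss_frac <- rowMeans(is.na(m))
  vars <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else stats::var(x)
  })
  keep <- miss_frac <= max_missing_frac & vars >= min_variance
  if (!any(keep)) {
    stop_gliofuse("QC removed every gene (empty panel)",
                  "gliofuse_empty_panel_error")
  }
  dropped <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  med <- apply(m, 1, stats::median, na.rm = TRUE)
  for (g in which(rowSums(is.na(m)) > 0)) m[g, is.na(m[g, ])] <- med[g]
  out <- matrix_to_profiles(m)
  attr(out, "dropped_genes") <- dropped
  out
}

#' Read an expression table (genes x patients) from TSV/CSV
#'
#' The first column holds gene symbols; remaining columns are patients.
#'
#' @param path path to a `.tsv` or `.csv` file.
#' @return A list of [expression_profile] objects.
#' @export
read_expression_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  matrix_to_profiles(m)
}

#' Write a cohort of expression profiles as a TSV table
#'
#' @param profiles list of [expression_profile] objects sharing a gene index.
#' @param path output path.
#' @param digits significant digits used for formatting (fixed so identical
#'   inputs produce byte-identical files).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(profiles, path, digits = 10) {
  m <- profiles_to_matrix(profiles)
  df <- data.frame(gene = rownames(m),
                   signif(m, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
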