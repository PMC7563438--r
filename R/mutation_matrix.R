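#' Binarized sample-by-gene mutation matrix
#'
#' The central data container: a binary matrix `X` with `N` samples in rows
#' and `Nd` genes in columns, together with sample identifiers, gene symbols
#' and a class label per sample.  Columns are ordered by non-increasing total
#' mutation count across samples (ties broken by gene symbol), the ordering
#' used throughout for gene ranking and display.
#'
#' @param X binary (0/1) numeric or integer matrix, samples in rows.
#' @param sample_ids character vector of unique sample identifiers, length
#'   `nrow(X)`.
#' @param gene_symbols character vector of unique gene symbols, length
#'   `ncol(X)`.
#' @param labels integer vector of 0-based class indices, length `nrow(X)`.
#' @param class_names character vector naming the classes; class index `i`
#'   maps to `class_names[i + 1]`.
#' @param reorder_genes if `TRUE` (default), columns are sorted by descending
#'   total mutation count with lexicographic tie-break; if `FALSE` the given
#'   order is validated instead.
#'
#' @return An object of class `mutation_matrix`: a list with elements `X`
#'   (integer matrix with dimnames), `sample_ids`, `gene_symbols`, `labels`,
#'   `class_names`.
#' @export
mutation_matrix <- function(X, sample_ids, gene_symbols, labels,
                            class_names = c("LUAD", "LUSC"),
                            reorder_genes = TRUE) {
  X <- as.matrix(X)
  if (!all(X %in% c(0L, 1L)))
    stopf("matrix entries must all be 0 or 1")
  storage.mode(X) <- "integer"
  if (length(sample_ids) != nrow(X))
    stopf("'sample_ids' length (%d) != nrow(X) (%d)", length(sample_ids), nrow(X))
  if (length(gene_symbols) != ncol(X))
    stopf("'gene_symbols' length (%d) != ncol(X) (%d)", length(gene_symbols), ncol(X))
  if (anyDuplicated(sample_ids)) stopf("'sample_ids' must be unique")
  if (anyDuplicated(gene_symbols)) stopf("'gene_symbols' must be unique")
  labels <- as.integer(labels)
  if (length(labels) != nrow(X) || anyNA(labels) ||
      any(labels < 0L) || any(labels >= length(class_names)))
    stopf("'labels' must be 0-based class indices in [0, %d] for every sample",
          length(class_names) - 1L)
  if (reorder_genes) {
    ord <- gene_count_order(colSums(X), gene_symbols)
    X <- X[, ord, drop = FALSE]
    gene_symbols <- gene_symbols[ord]
  } else {
    cnt <- colSums(X)
    if (is.unsorted(rev(cnt)))
      stopf("gene columns are not in non-increasing mutation-count order")
  }
  dimnames(X) <- list(sample_ids, gene_symbols)
  structure(
    list(X = X, sample_ids = as.character(sample_ids),
         gene_symbols = as.character(gene_symbols),
         labels = labels, class_names = as.character(class_names)),
    class = "mutation_matrix")
}

# descending count, ties by gene symbol
gene_count_order <- function(counts, symbols) order(-counts, symbols)

#' @export
print.mutation_matrix <- function(x, ...) {
  tab <- table(factor(x$class_names[x$labels + 1L], levels = x$class_names))
  cat(sprintf("mutation_matrix: %d samples x %d genes\n", nrow(x$X), ncol(x$X)))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  matrix density: %.4f\n", mean(x$X)))
  invisible(x)
}

#' @export
dim.mutation_matrix <- function(x) dim(x$X)

#' Subset samples of a mutation matrix
#'
#' Keeps the given samples (by index) in the given order; the gene order is
#' left untouched so that models trained on one subset stay aligned with
#' another.
#'
#' @param m a [mutation_matrix()].
#' @param idx integer vector of sample indices.
#' @return A `mutation_matrix` over the selected samples.
#' @export
subset_samples <- function(m, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > nrow(m$X)))
    stopf("sample indices out of range 1..%d", nrow(m$X))
  structure(
    list(X = m$X[idx, , drop = FALSE], sample_ids = m$sample_ids[idx],
         gene_symbols = m$gene_symbols, labels = m$labels[idx],
         class_names = m$class_names),
    class = "mutation_matrix")
}

#' Write a mutation matrix as dense TSV files
#'
#' Persists the binary matrix as a dense TSV (one row per sample, header =
#' gene symbols, first column `sample_id`) and the labels as a second TSV
#' with columns `sample_id` and `label` (class name).
#'
#' @param m a [mutation_matrix()].
#' @param matrix_path,labels_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_mutation_matrix <- function(m, matrix_path, labels_path) {
  dt <- data.table::as.data.table(m$X)
  dt <- cbind(data.table::data.table(sample_id = m$sample_ids), dt)
  data.table::fwrite(dt, matrix_path, sep = "\t")
  lab <- data.table::data.table(sample_id = m$sample_ids,
                                label = m$class_names[m$labels + 1L])
  data.table::fwrite(lab, labels_path, sep = "\t")
  invisible(c(matrix_path, labels_path))
}

#' Read a mutation matrix written by [write_mutation_matrix()]
#'
#' @param matrix_path,labels_path file paths produced by
#'   [write_mutation_matrix()].
#' @param class_names class vocabulary in index order.
#' @return A [mutation_matrix()].
#' @export
read_mutation_matrix <- function(matrix_path, labels_path,
                                 class_names = c("LUAD", "LUSC")) {
  dt <- data.table::fread(matrix_path, sep = "\t")
  lab <- data.table::fread(labels_path, sep = "\t")
  ids <- dt[["sample_id"]]
  X <- as.matrix(dt[, -1L])
  lmap <- match(lab$label, class_names) - 1L
  if (anyNA(lmap))
    stopf("labels file contains values outside the class vocabulary: %s",
          paste(unique(lab$label[is.na(lmap)]), collapse = ", "))
  labels <- lmap[match(ids, lab$sample_id)]
  if (anyNA(labels)) stopf("labels file does not cover every sample")
  mutation_matrix(X, ids, colnames(X), labels, class_names,
                  reorder_genes = FALSE)
}
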