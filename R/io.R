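#' Read a MAF-style mutation table
#'
#' Reads a tab-separated mutation table and returns one record per variant
#' row with the three fields used downstream: gene symbol, sample barcode and
#' variant classification.  Column names are configurable through `columns`
#' and default to the MAF vocabulary.  Rows with an empty gene symbol or
#' sample barcode are skipped and their count reported via `message()`.
#'
#' @param path TSV file path.
#' @param columns named character vector mapping the roles `gene`, `sample`,
#'   `class` to column names in the file header.
#' @return A `data.frame` with columns `gene_symbol`, `sample_id`,
#'   `variant_classification` (one row per surviving input row).
#' @export
read_mutation_table <- function(path,
                                columns = c(gene = "Hugo_Symbol",
                                            sample = "Tumor_Sample_Barcode",
                                            class = "Variant_Classification")) {
  if (!file.exists(path)) stopf("mutation table not found: %s", path)
  need <- c("gene", "sample", "class")
  if (!all(need %in% names(columns)))
    stopf("'columns' must name %s", paste(need, collapse = ", "))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  for (role in need) {
    if (!columns[[role]] %in% names(dt))
      stopf("mutation table header lacks the %s column '%s'",
            role, columns[[role]])
  }
  rec <- data.frame(
    gene_symbol = dt[[columns[["gene"]]]],
    sample_id = dt[[columns[["sample"]]]],
    variant_classification = dt[[columns[["class"]]]],
    stringsAsFactors = FALSE)
  bad <- !nzchar(rec$gene_symbol) | !nzchar(rec$sample_id) |
    is.na(rec$gene_symbol) | is.na(rec$sample_id)
  if (any(bad)) {
    message(sprintf("read_mutation_table: skipped %d row(s) with empty gene or sample",
                    sum(bad)))
    rec <- rec[!bad, , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}

#' Read clinical histology labels
#'
#' Maps each sample barcode to a 0-based class index through a label
#' vocabulary (default `LUAD` = 0, `LUSC` = 1).  Unknown label values and
#' samples listed twice with conflicting labels are errors.
#'
#' @param path TSV file path.
#' @param columns named character vector mapping roles `sample` and `label`
#'   to column names.
#' @param label_vocabulary named integer vector: class name -> 0-based index.
#' @return Named integer vector of class indices, names = sample ids, with
#'   attribute `class_names` (vocabulary names in index order).
#' @export
read_clinical_labels <- function(path,
                                 columns = c(sample = "Tumor_Sample_Barcode",
                                             label = "Histology"),
                                 label_vocabulary = c(LUAD = 0L, LUSC = 1L)) {
  if (!file.exists(path)) stopf("clinical table not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  for (role in c("sample", "label")) {
    if (!columns[[role]] %in% names(dt))
      stopf("clinical table header lacks the %s column '%s'",
            role, columns[[role]])
  }
  ids <- dt[[columns[["sample"]]]]
  raw <- dt[[columns[["label"]]]]
  unknown <- !(raw %in% names(label_vocabulary))
  if (any(unknown))
    stopf("unknown label value(s) %s at row(s) %s",
          paste(unique(raw[unknown]), collapse = ", "),
          paste(utils::head(which(unknown), 10L), collapse = ", "))
  cls <- as.integer(label_vocabulary[raw])
  if (anyDuplicated(ids)) {
    agg <- tapply(cls, ids, function(v) length(unique(v)))
    conflict <- names(agg)[agg > 1L]
    if (length(conflict))
      stopf("conflicting labels for sample(s): %s",
            paste(conflict, collapse = ", "))
    keep <- !duplicated(ids)
    ids <- ids[keep]
    cls <- cls[keep]
  }
  names(cls) <- ids
  class_names <- names(sort(label_vocabulary))
  attr(cls, "class_names") <- class_names
  cls
}

#' Drop variant classes with minimal biological impact
#'
#' Removes records whose variant classification is in the excluded set.  The
#' default excludes silent and splice-region alterations; the set is
#' configurable so stricter MAF vocabularies (Intron, 3'UTR, 5'UTR, RNA,
#' IGR, ...) can be added.
#'
#' @param records data.frame from [read_mutation_table()].
#' @param excluded_classes character vector of variant classifications to
#'   drop.
#' @return The surviving records, row names reset.
#' @export
filter_records <- function(records,
                           excluded_classes = c("Silent", "Splice_Site",
                                                "Splice_Region")) {
  keep <- !(records$variant_classification %in% excluded_classes)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the binarized, count-ordered mutation matrix
#'
#' Counts surviving mutation records per (sample, gene), binarizes to
#' presence/absence, and orders gene columns by descending total mutation
#' count (ties by gene symbol).  Samples are the labeled samples in the order
#' of `labels`; samples with a clinical label but no surviving mutation are
#' kept as all-zero rows unless `keep_unmutated_samples = FALSE`.
#'
#' @param records filtered records (see [filter_records()]).
#' @param labels named class-index vector from [read_clinical_labels()].
#' @param keep_unmutated_samples keep labeled samples that have no surviving
#'   record (default `TRUE`).
#' @return A [mutation_matrix()].
#' @export
build_mutation_matrix <- function(records, labels,
                                  keep_unmutated_samples = TRUE) {
  unlabeled <- setdiff(unique(records$sample_id), names(labels))
  if (length(unlabeled))
    stopf("record(s) for sample(s) without a clinical label: %s",
          paste(utils::head(unlabeled, 10L), collapse = ", "))
  sample_ids <- names(labels)
  if (!keep_unmutated_samples)
    sample_ids <- sample_ids[sample_ids %in% records$sample_id]
  genes <- sort(unique(records$gene_symbol))
  X <- matrix(0L, length(sample_ids), length(genes),
              dimnames = list(sample_ids, genes))
  if (nrow(records)) {
    i <- match(records$sample_id, sample_ids)
    j <- match(records$gene_symbol, genes)
    X[cbind(i, j)] <- 1L
  }
  class_names <- attr(labels, "class_names") %||% c("LUAD", "LUSC")
  mutation_matrix(X, sample_ids, genes, unname(labels[sample_ids]),
                  class_names = class_names, reorder_genes = TRUE)
}

#' Largest sample count divisible into k equal folds
#'
#' Returns the largest multiple of `k` not exceeding `n`; samples beyond that
#' index (in the given cohort order) are the ones to drop so that every
#' cross-validation fold has identical size.
#'
#' @param n number of available samples.
#' @param k number of folds.
#' @return Integer, `k * floor(n / k)`.
#' @export
truncate_to_equal_folds <- function(n, k) {
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  if (n < k) stopf("need at least k = %d samples, got n = %d", k, n)
  as.integer(k * (n %/% k))
}

#' Assign samples to k equal cross-validation folds
#'
#' @param m a [mutation_matrix()] whose sample count is divisible by `k`
#'   (apply [truncate_to_equal_folds()] and [subset_samples()] first).
#' @param k number of folds.
#' @param shuffle_seed integer seed for a random permutation of samples
#'   before assignment, or `NULL` for contiguous blocks in sample order.
#' @return An object of class `cv_split`: list with `fold` (fold index 1..k
#'   per sample) and `k`.
#' @export
make_cv_splits <- function(m, k, shuffle_seed = NULL) {
  k <- check_count(k, "k")
  n <- nrow(m$X)
  if (n %% k != 0L)
    stopf("sample count %d not divisible by k = %d; truncate first", n, k)
  ord <- seq_len(n)
  if (!is.null(shuffle_seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(check_count(shuffle_seed, "shuffle_seed",
                         min = -.Machine$integer.max))
    ord <- sample.int(n)
  }
  fold <- integer(n)
  fold[ord] <- rep(seq_len(k), each = n %/% k)
  structure(list(fold = fold, k = k), class = "cv_split")
}
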