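#' Specification for a synthetic binary mutation cohort
#'
#' Describes a two-class cohort of binary mutation profiles with a minority
#' of "planted" class-associated genes, emulating the statistical structure
#' of a binarized somatic-mutation matrix: entries in \{0,1\}, balanced
#' classes, and per-gene mutation probabilities that differ between classes
#' only for the planted genes.
#'
#' The defaults describe the strong-signal study cohort used throughout the
#' package's tests and examples: 400 samples, 200 genes, 20 planted genes per
#' class mutated at rate 0.4 in their associated class and 0.05 in the other,
#' and a 0.05 background rate everywhere else.
#'
#' @param n_samples even number of samples (classes are exactly balanced).
#' @param n_genes total number of genes; at least `2 * n_dominant_per_class`.
#' @param n_dominant_per_class number of planted genes per class.
#' @param p_high mutation probability of a planted gene in its associated
#'   class.
#' @param p_low mutation probability of the same gene in the other class;
#'   must satisfy `0 <= p_low < p_high <= 1`.
#' @param p_background mutation probability of every non-planted gene in both
#'   classes.
#' @param seed integer seed for the cohort's single pseudo-random stream.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 400L, n_genes = 200L,
                           n_dominant_per_class = 20L,
                           p_high = 0.4, p_low = 0.05, p_background = 0.05,
                           seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  if (n_samples %% 2L != 0L)
    stopf("'n_samples' must be even (balanced classes), got %d", n_samples)
  n_genes <- check_count(n_genes, "n_genes")
  n_dominant_per_class <- check_count(n_dominant_per_class,
                                      "n_dominant_per_class", min = 0L)
  if (2L * n_dominant_per_class > n_genes)
    stopf("'n_dominant_per_class': need 2 * %d <= n_genes = %d",
          n_dominant_per_class, n_genes)
  p_high <- check_prob(p_high, "p_high")
  p_low <- check_prob(p_low, "p_low")
  p_background <- check_prob(p_background, "p_background")
  if (p_low >= p_high)
    stopf("'p_low' must be strictly below 'p_high' (got %g >= %g)",
          p_low, p_high)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_dominant_per_class = n_dominant_per_class,
                 p_high = p_high, p_low = p_low, p_background = p_background,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic mutation cohort with planted class-associated genes
#'
#' Draws a balanced binary cohort from a [synthetic_spec()].  Class labels
#' alternate deterministically (odd samples class 0 "LUAD-like", even samples
#' class 1 "LUSC-like") so that contiguous cross-validation folds stay
#' balanced; gene columns are then drawn Bernoulli in index order from a
#' single stream keyed by `spec$seed`.  The first `n_dominant_per_class`
#' genes are associated with class 0, the next block with class 1, and the
#' remainder are background.  Finally the columns are re-ordered by
#' descending mutation count, the canonical gene order of
#' [mutation_matrix()].
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `synthetic_cohort`: a list with `matrix` (a
#'   [mutation_matrix()]), `class_a_genes` and `class_b_genes` (character
#'   vectors of planted gene symbols), and `spec`.
#' @export
generate_synthetic_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stopf("'spec' must be a synthetic_spec object")
  n <- spec$n_samples
  d <- spec$n_genes
  ndom <- spec$n_dominant_per_class
  labels <- rep_len(c(0L, 1L), n)
  gene_symbols <- sprintf("G%06d", seq_len(d))
  class_a <- gene_symbols[seq_len(ndom)]
  class_b <- gene_symbols[ndom + seq_len(ndom)]
  # per-gene mutation probability by class: column j, class c
  p_of <- function(j, cls) {
    if (j <= ndom)            # class-0-associated
      ifelse(cls == 0L, spec$p_high, spec$p_low)
    else if (j <= 2L * ndom)  # class-1-associated
      ifelse(cls == 1L, spec$p_high, spec$p_low)
    else spec$p_background
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  X <- matrix(0L, n, d)
  for (j in seq_len(d)) {
    X[, j] <- as.integer(stats::runif(n) < p_of(j, labels))
  }
  m <- mutation_matrix(X, sprintf("S%06d", seq_len(n)), gene_symbols, labels,
                       class_names = c("LUAD", "LUSC"), reorder_genes = TRUE)
  structure(list(matrix = m, class_a_genes = class_a, class_b_genes = class_b,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples x %d genes, %d planted genes/class (seed %d)\n",
    x$spec$n_samples, x$spec$n_genes, x$spec$n_dominant_per_class,
    x$spec$seed))
  print(x$matrix)
  invisible(x)
}

#' Serialize a cohort to the MAF-style TSV pair the readers consume
#'
#' Writes a long-format mutation table (one row per mutated sample/gene cell,
#' columns `Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Classification`
#' with the non-silent placeholder `Missense_Mutation`) and a clinical table
#' (`Tumor_Sample_Barcode`, `Histology`), the exact pair accepted by
#' [read_mutation_table()] and [read_clinical_labels()], enabling round-trip
#' tests.
#'
#' @param cohort a `synthetic_cohort` or a bare [mutation_matrix()].
#' @param mutation_path,clinical_path output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_tsv <- function(cohort, mutation_path, clinical_path) {
  m <- if (inherits(cohort, "synthetic_cohort")) cohort$matrix else cohort
  if (!inherits(m, "mutation_matrix"))
    stopf("'cohort' must be a synthetic_cohort or mutation_matrix")
  hit <- which(m$X == 1L, arr.ind = TRUE)
  mut <- data.table::data.table(
    Hugo_Symbol = m$gene_symbols[hit[, "col"]],
    Tumor_Sample_Barcode = m$sample_ids[hit[, "row"]],
    Variant_Classification = "Missense_Mutation")
  data.table::setorder(mut, Tumor_Sample_Barcode, Hugo_Symbol)
  data.table::fwrite(mut, mutation_path, sep = "\t")
  clin <- data.table::data.table(
    Tumor_Sample_Barcode = m$sample_ids,
    Histology = m$class_names[m$labels + 1L])
  data.table::fwrite(clin, clinical_path, sep = "\t")
  invisible(c(mutation_path, clinical_path))
}
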