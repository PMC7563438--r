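#' Extract per-gene hidden representations from a trained model
#'
#' Since the input is binary, switching gene `i` on contributes row `i` of
#' the effective first-layer matrix to the pre-activation of the hidden
#' layer, so that row is the gene's learned embedding: row `i` of `We` for
#' plain MLP and diet variants, and `Ue[i] * We[i, ]` for EIS variants
#' (the scaling is absorbed into the embedding).
#'
#' @param state a [model_state][initialize_state()] with cached fat weights
#'   (e.g. the `state` of a [train_fold()] fit).
#' @param gene_symbols optional character vector of row names, length `Nd`.
#' @return A numeric matrix `Nd x Nh` of class `gene_embeddings`.
#' @export
extract_hidden_representations <- function(state, gene_symbols = NULL) {
  We <- state$cache$We
  if (is.null(We)) stopf("fat weights not cached; call compute_fat_weights()")
  E <- if (is_eis(state$config)) We * state$params$Ue else We
  if (!is.null(gene_symbols)) {
    if (length(gene_symbols) != nrow(E))
      stopf("'gene_symbols' length %d != Nd = %d", length(gene_symbols), nrow(E))
    rownames(E) <- gene_symbols
  }
  class(E) <- c("gene_embeddings", class(E))
  E
}

#' Centered PCA of gene embeddings
#'
#' Standard centered principal component analysis of the embedding rows.
#' Component signs are fixed deterministically: each component's
#' largest-magnitude coordinate is made positive (with its scores flipped
#' accordingly), so decompositions are reproducible across runs.
#'
#' @param embeddings `Nd x Nh` matrix from
#'   [extract_hidden_representations()].
#' @param n_components number of components to keep (default: all,
#'   `min(Nd, Nh)`).
#' @return An object of class `pca_basis`: list with `components`
#'   (`Nh x n_components`, orthonormal columns), `scores`
#'   (`Nd x n_components`), `center` (`Nh`), `explained_variance`
#'   (fractions) and `n_components`.
#' @export
pca_decompose <- function(embeddings, n_components = NULL) {
  E <- unclass(embeddings)
  max_nc <- min(dim(E))
  n_components <- if (is.null(n_components)) max_nc
                  else check_count(n_components, "n_components")
  if (n_components > max_nc)
    stopf("'n_components' = %d exceeds min(Nd, Nh) = %d", n_components, max_nc)
  pc <- stats::prcomp(E, center = TRUE, scale. = FALSE)
  if (all(pc$sdev < 1e-12))
    warning("embeddings have zero variance; components are arbitrary up to the documented sign rule")
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  sco <- pc$x[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    jmax <- which.max(abs(rot[, k]))
    if (rot[jmax, k] < 0) {
      rot[, k] <- -rot[, k]
      sco[, k] <- -sco[, k]
    }
  }
  ev <- pc$sdev^2
  structure(list(components = rot, scores = sco, center = pc$center,
                 explained_variance = ev / sum(ev),
                 n_components = n_components),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("pca_basis: %d components over %d genes\n",
              x$n_components, nrow(x$scores)))
  ev <- x$explained_variance[seq_len(min(5L, x$n_components))]
  cat("  explained variance:", paste(sprintf("%.3f", ev), collapse = " "), "\n")
  invisible(x)
}

#' Rank-K approximation of the gene embeddings
#'
#' Reconstructs every embedding from the selected principal components:
#' `h_i ~ center + sum_{k in K} s_k[i] * PC_k`.  The centering mean is
#' re-added by default (the standard rank-K reconstruction);
#' `include_mean = FALSE` gives the literal mean-free combination.
#'
#' @param basis a [pca_decompose()] result.
#' @param K integer vector of component indices (may be empty: every row
#'   becomes the mean vector).
#' @param include_mean re-add the centering mean (default `TRUE`).
#' @return A `gene_embeddings` matrix `Nd x Nh`.
#' @export
approximate_embeddings <- function(basis, K, include_mean = TRUE) {
  K <- as.integer(K)
  if (length(K) && (any(K < 1L) || any(K > basis$n_components)))
    stopf("component index set K must lie within 1..%d", basis$n_components)
  Nd <- nrow(basis$scores)
  E <- if (length(K))
    basis$scores[, K, drop = FALSE] %*% t(basis$components[, K, drop = FALSE])
  else matrix(0, Nd, length(basis$center))
  if (include_mean) E <- sweep(E, 2L, basis$center, "+")
  rownames(E) <- rownames(basis$scores)
  class(E) <- c("gene_embeddings", class(E))
  E
}

#' Validation accuracy with a substituted first-layer matrix
#'
#' Replaces the model's effective first-layer matrix (fat weights with any
#' input scaling already absorbed, as in
#' [extract_hidden_representations()]) by the given embedding matrix and
#' runs the standard forward pass on a validation set:
#' `H = relu(X E [+ be])`, `Yhat = softmax(H Wd + bd)`.
#'
#' @param state a trained [model_state][initialize_state()].
#' @param embeddings `Nd x Nh` matrix (e.g. from
#'   [approximate_embeddings()]).
#' @param validation a [mutation_matrix()] of held-out samples.
#' @return Arg-max classification accuracy in `[0, 1]`.
#' @export
evaluate_approximation <- function(state, embeddings, validation) {
  E <- unclass(embeddings)
  cfg <- state$config
  if (nrow(E) != cfg$n_features || ncol(E) != cfg$n_hidden)
    stopf("embeddings are %d x %d but the model expects %d x %d",
          nrow(E), ncol(E), cfg$n_features, cfg$n_hidden)
  X <- validation$X
  storage.mode(X) <- "double"
  A <- X %*% E
  if (!is_diet(cfg)) A <- sweep(A, 2L, state$params$be, "+")
  H <- relu(A)
  Z <- sweep(H %*% state$params$Wd, 2L, state$params$bd, "+")
  pred <- row_argmax(Z) - 1L
  mean(pred == validation$labels)
}

#' Per-gene dominance by two-sample t-test
#'
#' For every gene, compares the binary mutation indicator between the two
#' classes with a two-sided Welch t-test and labels the gene with the class
#' of higher mutation frequency when `p < alpha`, else `"neither"`.  Genes
#' constant within both classes get `p = 1` when the class frequencies are
#' equal and `p = 0` when they are maximally separated (e.g. always mutated
#' in one class, never in the other).
#'
#' @param m a [mutation_matrix()] with both classes present.
#' @param alpha significance level (default 0.05).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   before grouping; default `"none"` (raw p-values).
#' @return A `data.frame` with columns `gene_symbol`, `freq_<classA>`,
#'   `freq_<classB>`, `mean_diff` (class A minus class B), `p_value`, and
#'   `group` (factor: the two class-dominant labels and `"neither"`).
#' @export
dominance_ttest <- function(m, alpha = 0.05, adjust = "none") {
  a_idx <- m$labels == 0L
  b_idx <- m$labels == 1L
  if (!any(a_idx) || !any(b_idx))
    stopf("both classes must be present for the dominance t-test")
  Xa <- m$X[a_idx, , drop = FALSE]
  Xb <- m$X[b_idx, , drop = FALSE]
  fa <- colMeans(Xa)
  fb <- colMeans(Xb)
  p <- vapply(seq_len(ncol(m$X)), function(j) {
    xa <- Xa[, j]; xb <- Xb[, j]
    if (stats::var(xa) == 0 && stats::var(xb) == 0)
      return(if (mean(xa) == mean(xb)) 1 else 0)
    stats::t.test(xa, xb, var.equal = FALSE)$p.value
  }, numeric(1))
  p_used <- stats::p.adjust(p, method = adjust)
  lab_a <- paste0(m$class_names[1L], "-dominant")
  lab_b <- paste0(m$class_names[2L], "-dominant")
  grp <- ifelse(p_used >= alpha, "neither", ifelse(fa > fb, lab_a, lab_b))
  out <- data.frame(gene_symbol = m$gene_symbols,
                    fa, fb,
                    mean_diff = fa - fb,
                    p_value = p_used,
                    group = factor(grp, levels = c(lab_a, lab_b, "neither")),
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("freq_", m$class_names)
  rownames(out) <- NULL
  out
}

#' Rank genes by principal-component score
#'
#' Sorts genes by their score on one principal component and returns the
#' `top_n` most positive and most negative genes; along a class-dominant
#' component these sign groups read as preferences for the two classes.
#' Ties are broken lexicographically by gene symbol.
#'
#' @param basis a [pca_decompose()] result with gene symbols as score row
#'   names.
#' @param pc_index component to rank by (default 2, the class-preference
#'   axis in the lung-histology analysis).
#' @param top_n list length per sign (default 10).
#' @return List with `positive` and `negative`, each a `data.frame` of
#'   `gene_symbol` and `score` sorted by decreasing magnitude.
#' @export
rank_genes_by_pc_score <- function(basis, pc_index = 2L, top_n = 10L) {
  pc_index <- check_count(pc_index, "pc_index")
  if (pc_index > basis$n_components)
    stopf("pc_index = %d exceeds available components (%d)",
          pc_index, basis$n_components)
  top_n <- check_count(top_n, "top_n")
  s <- basis$scores[, pc_index]
  genes <- rownames(basis$scores) %||% sprintf("row%d", seq_along(s))
  pos_ord <- order(-s, genes)
  neg_ord <- order(s, genes)
  take <- function(ord) {
    ord <- utils::head(ord, top_n)
    data.frame(gene_symbol = genes[ord], score = unname(s[ord]),
               stringsAsFactors = FALSE)
  }
  list(positive = take(pos_ord), negative = take(neg_ord))
}

#' 2D t-SNE projection of gene embeddings
#'
#' Plot-oriented nonlinear projection of the embedding rows, deterministic
#' for a given seed.  The perplexity is capped at the largest value t-SNE
#' admits for the number of genes.
#'
#' @param embeddings `Nd x Nh` matrix (`Nd >= 3`).
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity (default 30, capped automatically).
#' @param ... further arguments to [Rtsne::Rtsne()].
#' @return Numeric matrix `Nd x 2` with the embedding row names.
#' @export
project_tsne <- function(embeddings, seed = 1L, perplexity = 30, ...) {
  E <- unclass(embeddings)
  if (nrow(E) < 3L) stopf("t-SNE projection needs at least 3 genes")
  perplexity <- min(perplexity, floor((nrow(E) - 1) / 3))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(check_count(seed, "seed", min = -.Machine$integer.max))
  fit <- Rtsne::Rtsne(E, dims = 2L, perplexity = perplexity,
                      check_duplicates = FALSE, ...)
  out <- fit$Y
  rownames(out) <- rownames(E)
  colnames(out) <- c("tsne1", "tsne2")
  out
}
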