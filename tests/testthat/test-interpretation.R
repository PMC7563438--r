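# small trained model shared within this file
fit_tiny_model <- function(variant = "diet_eis", epochs = 15L) {
  coh <- tiny_cohort(seed = 6)
  m <- coh$matrix
  split <- make_cv_splits(m, 5)
  ncfg <- network_config(ncol(m$X), n_hidden = 8, aux_hidden = 6,
                         variant = variant)
  tcfg <- train_config(batch_size = 16, max_epochs = epochs,
                       eval_window = c(1, epochs), seed = 4)
  list(fit = train_fold(m, split, 1, ncfg, tcfg), m = m,
       val = subset_samples(m, which(split$fold == 1)))
}

test_that("hidden representations are We rows with the input scaling absorbed", {
  cfg <- network_config(3, n_hidden = 2, variant = "mlp_eis")
  st <- initialize_state(cfg, seed = 1)
  st$params$We <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  st$params$Ue <- c(2, 1, 0.5)
  st <- compute_fat_weights(st)
  E <- extract_hidden_representations(st, c("g1", "g2", "g3"))
  expect_equal(unname(unclass(E)),
               matrix(c(2, 2, 1.5, 8, 5, 3), 3, 2))
  st$params$Ue <- c(2, 0, 0.5)
  st <- compute_fat_weights(st)
  E0 <- extract_hidden_representations(st)
  expect_equal(unname(E0[2, ]), c(0, 0))
  # unit scaling reproduces the unscaled extraction
  st$params$Ue <- rep(1, 3)
  st <- compute_fat_weights(st)
  expect_equal(unclass(extract_hidden_representations(st)), st$params$We)
})

test_that("PCA decomposition matches an independent eigendecomposition", {
  E <- matrix(c(1, 2, 3, 7,
                1, 3, 2, 9), 4, 2)
  basis <- pca_decompose(E)
  # oracle: eigenvectors of the sample covariance of centered data
  C <- scale(E, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(E))
  V <- eig$vectors
  for (k in 1:2) if (V[which.max(abs(V[, k])), k] < 0) V[, k] <- -V[, k]
  expect_equal(unname(basis$components), V, tolerance = 1e-10)
  expect_equal(unname(basis$scores), unname(C %*% V), tolerance = 1e-10)
  expect_equal(basis$explained_variance,
               eig$values / sum(eig$values), tolerance = 1e-10)
  # orthonormality
  expect_equal(crossprod(basis$components), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rank-1 data loads entirely on the first component", {
  d <- c(-2, 0, 1, 4)
  E <- cbind(1 + 2 * d, 3 - d)   # a line through the mean
  basis <- pca_decompose(E)
  expect_equal(basis$explained_variance[1], 1.0, tolerance = 1e-12)
  # K = (1) reconstructs exactly: no residual variance
  expect_equal(unclass(approximate_embeddings(basis, 1L)), E,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA scores are invariant to translating all embeddings", {
  set.seed(12)
  E <- matrix(rnorm(60), 20, 3)
  shifted <- sweep(E, 2L, c(5, -3, 0.5), "+")
  expect_equal(pca_decompose(E)$scores, pca_decompose(shifted)$scores,
               tolerance = 1e-8)
})

test_that("approximation with all components is the identity; empty K is the mean", {
  set.seed(13)
  E <- matrix(rnorm(80), 16, 5)
  rownames(E) <- sprintf("g%02d", 1:16)
  basis <- pca_decompose(E)
  expect_equal(unclass(approximate_embeddings(basis, seq_len(basis$n_components))),
               E, tolerance = 1e-6)
  Em <- approximate_embeddings(basis, integer(0))
  for (i in 1:16) expect_equal(unname(Em[i, ]), unname(colMeans(E)))
  expect_error(approximate_embeddings(basis, 6L), "1..5")
  # degenerate input warns
  expect_warning(pca_decompose(matrix(1, 5, 3)), "zero variance")
})

test_that("substituting the unmodified embeddings reproduces model accuracy", {
  tm <- fit_tiny_model()
  E <- extract_hidden_representations(tm$fit$state, tm$m$gene_symbols)
  acc_sub <- evaluate_approximation(tm$fit$state, E, tm$val)
  acc_std <- mean(predict_classes(tm$fit$state, tm$val$X) == tm$val$labels)
  expect_identical(acc_sub, acc_std)
  # full-rank PCA reconstruction preserves it too
  acc_full <- evaluate_approximation(
    tm$fit$state,
    approximate_embeddings(pca_decompose(E), seq_len(min(dim(E)))),
    tm$val)
  expect_identical(acc_full, acc_std)
})

test_that("all-zero embeddings collapse to the classifier-bias majority vote", {
  tm <- fit_tiny_model(variant = "diet", epochs = 5L)
  E0 <- matrix(0, ncol(tm$m$X), tm$fit$state$config$n_hidden)
  acc <- evaluate_approximation(tm$fit$state, E0, tm$val)
  pred <- which.max(tm$fit$state$params$bd) - 1L
  expect_equal(acc, mean(tm$val$labels == pred))
  expect_error(evaluate_approximation(tm$fit$state, E0[, 1:3], tm$val),
               "expects")
})

test_that("dominance t-test handles maximal separation and exact ties", {
  X <- cbind(sep = c(rep(1L, 10), rep(0L, 10)),
             tie = rep(c(1L, 0L), 10))
  m <- mutation_matrix(X, sprintf("S%02d", 1:20), c("sep", "tie"),
                       rep(c(0L, 1L), each = 10))
  dom <- dominance_ttest(m)
  sep_row <- dom[dom$gene_symbol == "sep", ]
  expect_lt(sep_row$p_value, 0.001)
  expect_equal(as.character(sep_row$group), "LUAD-dominant")
  tie_row <- dom[dom$gene_symbol == "tie", ]
  expect_equal(tie_row$p_value, 1)
  expect_equal(as.character(tie_row$group), "neither")
  one_class <- mutation_matrix(X[1:10, , drop = FALSE], sprintf("S%02d", 1:10),
                               c("sep", "tie"), rep(0L, 10))
  expect_error(dominance_ttest(one_class), "both classes")
})

test_that("dominance p-value matches the textbook Welch formula", {
  xa <- c(rep(1L, 12), rep(0L, 38))
  xb <- c(rep(1L, 3), rep(0L, 47))
  X <- cbind(g = c(xa, xb))
  m <- mutation_matrix(X, sprintf("S%03d", 1:100), "g",
                       rep(c(0L, 1L), each = 50))
  dom <- dominance_ttest(m)
  # independent oracle: Welch statistic and Satterthwaite df by hand
  va <- stats::var(xa); vb <- stats::var(xb)
  tstat <- (mean(xa) - mean(xb)) / sqrt(va / 50 + vb / 50)
  df <- (va / 50 + vb / 50)^2 /
    ((va / 50)^2 / 49 + (vb / 50)^2 / 49)
  p_oracle <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(dom$p_value, p_oracle, tolerance = 1e-6)
  expect_equal(as.character(dom$group), "LUAD-dominant")
})

test_that("directional call agrees with a brute-force permutation test", {
  x <- c(rep(1L, 8), rep(0L, 2), rep(1L, 1), rep(0L, 9))
  labels <- rep(c(0L, 1L), each = 10)
  m <- mutation_matrix(cbind(g = x), sprintf("S%02d", 1:20), "g", labels)
  dom <- dominance_ttest(m, alpha = 0.01)
  obs <- mean(x[labels == 0]) - mean(x[labels == 1])
  set.seed(17)
  null <- replicate(4000, {
    sh <- sample(labels)
    mean(x[sh == 0]) - mean(x[sh == 1])
  })
  p_perm <- mean(abs(null) >= abs(obs))
  expect_lt(p_perm, 0.01)
  expect_lt(dom$p_value, 0.01)
  expect_equal(as.character(dom$group),
               if (obs > 0) "LUAD-dominant" else "LUSC-dominant")
})

test_that("gene ranking by PC score sorts signs with lexicographic ties", {
  basis <- structure(list(
    components = diag(2), center = c(0, 0), n_components = 2L,
    explained_variance = c(0.7, 0.3),
    scores = matrix(c(3, -1, 0.5, 0, 0, 0), 3, 2,
                    dimnames = list(c("gene1", "gene2", "gene3"), NULL))),
    class = "pca_basis")
  r <- rank_genes_by_pc_score(basis, pc_index = 1L, top_n = 1L)
  expect_equal(r$positive$gene_symbol, "gene1")
  expect_equal(r$positive$score, 3)
  expect_equal(r$negative$gene_symbol, "gene2")
  # all-zero scores: deterministic lexicographic order on both sides
  r2 <- rank_genes_by_pc_score(basis, pc_index = 2L, top_n = 2L)
  expect_equal(r2$positive$gene_symbol, c("gene1", "gene2"))
  expect_equal(r2$negative$gene_symbol, c("gene1", "gene2"))
  expect_true(all(r2$positive$score == 0))
  expect_error(rank_genes_by_pc_score(basis, pc_index = 3L), "exceeds")
})

test_that("t-SNE layouts are shaped, seeded and separate planted clusters", {
  set.seed(19)
  E <- rbind(matrix(rnorm(40 * 4, mean = 0), 40, 4),
             matrix(rnorm(40 * 4, mean = 6), 40, 4))
  rownames(E) <- sprintf("g%03d", 1:80)
  z1 <- project_tsne(E, seed = 2, perplexity = 10)
  expect_equal(dim(z1), c(80L, 2L))
  z2 <- project_tsne(E, seed = 2, perplexity = 10)
  expect_identical(z1, z2)
  # separation sanity: mean silhouette of the true cluster labels positive
  grp <- rep(1:2, each = 40)
  sil <- cluster::silhouette(grp, stats::dist(z1))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
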