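# shared fixtures and independent oracles, built in code

# tiny cohort for fast mechanical tests
tiny_cohort <- function(seed = 3L, n_samples = 40L, n_genes = 20L,
                        n_dom = 4L) {
  generate_synthetic_cohort(synthetic_spec(
    n_samples = n_samples, n_genes = n_genes, n_dominant_per_class = n_dom,
    p_high = 0.6, p_low = 0.05, p_background = 0.1, seed = seed))
}

# the strong-signal study cohort (package defaults)
strong_cohort <- function(seed = 1L) {
  generate_synthetic_cohort(synthetic_spec(seed = seed))
}

# finite-difference gradient of the full objective wrt one parameter tensor
numeric_grad <- function(state, X, y, XT, nm, idx, eps = 1e-6) {
  lossat <- function(val) {
    s <- state
    s$params[[nm]][idx] <- val
    s <- compute_fat_weights(s, XT)
    dietnets:::backward_step(X, y, s)$loss
  }
  v <- state$params[[nm]][idx]
  (lossat(v + eps) - lossat(v - eps)) / (2 * eps)
}

# trained model cache shared by the slower tests: diet_eis (gamma = 0.1) on
# the strong-signal cohort, 5-fold CV, 200 epochs, seed 1 everywhere
.run_cache <- new.env(parent = emptyenv())

trained_strong_cv <- function() {
  if (is.null(.run_cache$cv)) {
    coh <- strong_cohort(seed = 1L)
    ncfg <- network_config(n_features = ncol(coh$matrix$X),
                           variant = "diet_eis", gamma = 0.1)
    tcfg <- train_config(max_epochs = 200L, eval_window = c(150L, 200L),
                         seed = 1L)
    .run_cache$cohort <- coh
    .run_cache$cv <- cross_validate(coh$matrix, ncfg, tcfg, k = 5L)
  }
  list(cohort = .run_cache$cohort, cv = .run_cache$cv)
}

# per-fold accuracies of a cv_result under a rank-K embedding approximation
approx_fold_accuracy <- function(cv, m, K = NULL) {
  vapply(cv$fits, function(fit) {
    E <- extract_hidden_representations(fit$state, m$gene_symbols)
    E_use <- if (is.null(K)) E else approximate_embeddings(pca_decompose(E), K)
    evaluate_approximation(fit$state, E_use, subset_samples(m, fit$val_idx))
  }, numeric(1))
}
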