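test_that("auxiliary network matches hand-computed affine + ReLU algebra", {
  # Nd = 3 genes, N_train = 2, Nj = 2, Nh = 1, weights set by hand
  XT <- matrix(c(1, 0, 1,
                 0, 1, 1), 3, 2)
  W1 <- matrix(c(1, 2, -1, 1), 2, 2)       # [[1,-1],[2,1]]
  b1 <- c(0.5, -0.5)
  W2 <- matrix(c(1, 2), 2, 1)
  b2 <- 0.25
  We <- auxiliary_forward(XT, W1, b1, W2, b2)
  expect_equal(dim(We), c(3L, 1L))
  expect_equal(as.vector(We), c(1.75, 3.75, 3.75))
})

test_that("all-zero transposed matrix propagates a constant bias row", {
  XT <- matrix(0, 5, 3)
  W1 <- matrix(rnorm(3 * 2), 3, 2); b1 <- c(0.3, -0.1)
  W2 <- matrix(rnorm(2 * 4), 2, 4); b2 <- rnorm(4)
  We <- auxiliary_forward(XT, W1, b1, W2, b2)
  for (i in 2:5) expect_equal(We[i, ], We[1, ])
  expect_error(auxiliary_forward(matrix(0, 5, 4), W1, b1, W2, b2), "width")
})

test_that("forward pass reproduces a hand-computed EIS example", {
  cfg <- network_config(3, n_hidden = 2, n_classes = 2, variant = "mlp_eis")
  st <- initialize_state(cfg, seed = 1)
  st$params$We <- matrix(c(1, 0, 1, 0, 1, -1), 3, 2)
  st$params$be <- c(0.1, -0.2)
  st$params$Ue <- c(2, 1, 0.5)
  st$params$Wd <- matrix(c(1, 0.5, -1, 0.5), 2, 2)
  st$params$bd <- c(0, 0.2)
  st <- compute_fat_weights(st)
  X <- matrix(c(1, 0, 0, 1, 1, 1), 2, 3)
  out <- net_forward(X, st)
  expect_equal(out$H, matrix(c(2.6, 0.6, 0, 0.3), 2, 2))
  # softmax over hand-computed logits (2.6, -2.4) and (0.75, -0.25)
  expect_equal(out$Y_hat[1, 1], 1 / (1 + exp(-5)), tolerance = 1e-12)
  expect_equal(out$Y_hat[2, 1], 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_null(out$X_hat)
})

test_that("softmax rows sum to one for random inputs on every variant", {
  for (variant in c("mlp", "mlp_eis", "diet", "diet_eis")) {
    cfg <- network_config(12, n_hidden = 5, n_classes = 3, aux_hidden = 4,
                          variant = variant, gamma = 0.1)
    st <- initialize_state(cfg, n_train = 6, seed = 2)
    XT <- matrix(rbinom(12 * 6, 1, 0.5), 12, 6)
    st <- compute_fat_weights(st, if (variant %in% c("diet", "diet_eis")) XT)
    X <- matrix(rbinom(7 * 12, 1, 0.4), 7, 12)
    out <- net_forward(X, st)
    expect_equal(rowSums(out$Y_hat), rep(1, 7), tolerance = 1e-6)
    expect_true(all(out$Y_hat >= 0))
    expect_true(all(out$X_hat > 0 & out$X_hat < 1))
  }
})

test_that("a zero input row yields H = 0 and the classifier-bias softmax", {
  cfg <- network_config(8, n_hidden = 4, n_classes = 2, variant = "diet")
  st <- initialize_state(cfg, n_train = 5, seed = 3)
  XT <- matrix(rbinom(8 * 5, 1, 0.5), 8, 5)
  st <- compute_fat_weights(st, XT)
  out <- net_forward(matrix(0, 1, 8), st)
  expect_equal(as.vector(out$H), rep(0, 4))
  expect_equal(as.vector(out$Y_hat),
               as.vector(exp(st$params$bd) / sum(exp(st$params$bd))),
               tolerance = 1e-12)
})

test_that("diet_eis with unit scaling equals diet on identical aux weights", {
  cfg_e <- network_config(15, n_hidden = 6, aux_hidden = 5,
                          variant = "diet_eis", gamma = 0.05)
  cfg_d <- network_config(15, n_hidden = 6, aux_hidden = 5,
                          variant = "diet", gamma = 0.05)
  st_e <- initialize_state(cfg_e, n_train = 8, seed = 7)
  st_d <- initialize_state(cfg_d, n_train = 8, seed = 7)
  # same draw order, Ue/Ur are deterministic ones
  expect_identical(st_e$params$Ge_W1, st_d$params$Ge_W1)
  XT <- matrix(rbinom(15 * 8, 1, 0.5), 15, 8)
  st_e <- compute_fat_weights(st_e, XT)
  st_d <- compute_fat_weights(st_d, XT)
  X <- matrix(rbinom(9 * 15, 1, 0.3), 9, 15)
  oe <- net_forward(X, st_e)
  od <- net_forward(X, st_d)
  expect_equal(oe$H, od$H, tolerance = 1e-6)
  expect_equal(oe$Y_hat, od$Y_hat, tolerance = 1e-6)
  expect_equal(oe$X_hat, od$X_hat, tolerance = 1e-6)
})

test_that("initialization is seed-deterministic and diet has no fat tensor", {
  cfg <- network_config(10, n_hidden = 4, aux_hidden = 3, variant = "diet_eis")
  a <- initialize_state(cfg, n_train = 6, seed = 5)
  b <- initialize_state(cfg, n_train = 6, seed = 5)
  expect_identical(a$params, b$params)
  dims <- lapply(a$params, dim)
  expect_false(any(vapply(dims, function(d)
    !is.null(d) && all(d == c(10L, 4L)), logical(1))))
  expect_equal(a$params$Ue, rep(1, 10))
})

test_that("parameter counting matches brute-force enumeration of tensors", {
  set.seed(99)
  for (variant in c("mlp", "mlp_eis", "diet", "diet_eis")) {
    for (recon in c(FALSE, TRUE)) {
      cfg <- network_config(sample(5:30, 1), n_hidden = sample(2:9, 1),
                            n_classes = sample(2:4, 1),
                            aux_hidden = sample(2:8, 1), variant = variant,
                            gamma = if (recon) 0.1 else 0)
      ntr <- sample(3:12, 1)
      st <- initialize_state(cfg, n_train = ntr, seed = 1)
      expect_identical(count_parameters(cfg, n_train = ntr),
                       as.integer(sum(vapply(st$params, length, integer(1)))),
                       info = paste(variant, recon))
    }
  }
})

test_that("parameter counts are monotone diet < diet_eis < mlp < mlp_eis at published sizes", {
  n <- vapply(c("diet", "diet_eis", "mlp", "mlp_eis"), function(v)
    count_parameters(network_config(17961, 128, 2, 256, variant = v),
                     n_train = 760), integer(1))
  expect_true(all(diff(n) > 0))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(21)
  for (variant in c("mlp_eis", "diet_eis")) {
    cfg <- network_config(6, n_hidden = 3, n_classes = 2, aux_hidden = 3,
                          variant = variant, gamma = 0.2, delta = 0.1)
    st <- initialize_state(cfg, n_train = 4, seed = 11)
    # nudge all biases off zero so no pre-activation sits exactly on the
    # ReLU kink, where central differences and subgradients disagree
    for (nm in grep("^b|_b", names(st$params), value = TRUE))
      st$params[[nm]] <- st$params[[nm]] + runif(length(st$params[[nm]]),
                                                 0.05, 0.2)
    X <- matrix(rbinom(5 * 6, 1, 0.4), 5, 6); storage.mode(X) <- "double"
    y <- rbinom(5, 1, 0.5)
    XT <- if (variant == "diet_eis")
      matrix(rbinom(6 * 4, 1, 0.5), 6, 4) else NULL
    st <- compute_fat_weights(st, XT)
    bw <- dietnets:::backward_step(X, y, st)
    for (nm in names(bw$grads)) {
      for (idx in unique(c(1L, length(st$params[[nm]])))) {
        expect_equal(bw$grads[[nm]][idx], numeric_grad(st, X, y, XT, nm, idx),
                     tolerance = 1e-5, info = paste(variant, nm, idx))
      }
    }
  }
})
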