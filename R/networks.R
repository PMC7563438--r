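#' Network architecture configuration
#'
#' Defines one of four fully-connected architectures over a binary
#' sample-by-gene matrix:
#'
#' * `mlp` — a three-layer perceptron whose first ("fat") weight matrix
#'   `We` (`Nd x Nh`) is a free parameter;
#' * `mlp_eis` — the same with element-wise input scaling: one learnable
#'   multiplicative scalar per gene (vector `Ue`, length `Nd`);
#' * `diet` — Diet Networks: `We` is not free but predicted row-by-row by a
#'   small auxiliary network `Ge` applied to the transposed training matrix,
#'   so each gene's weight vector is a function of that gene's mutation
#'   pattern across the training samples;
#' * `diet_eis` — Diet Networks plus element-wise input scaling.
#'
#' The optional reconstruction path decodes the hidden layer back to the
#' input through a mirror-image fat matrix `Wr` (free for MLP variants,
#' predicted by a second auxiliary network `Gr` for diet variants) with a
#' second scaling vector `Ur` for EIS variants.
#'
#' @param n_features `Nd`, number of input genes.
#' @param n_hidden `Nh`, hidden layer width (default 128).
#' @param n_classes `Nc`, number of output classes (default 2).
#' @param aux_hidden `Nj`, hidden width of the auxiliary networks
#'   (default 256; diet variants only).
#' @param variant one of `"diet_eis"`, `"diet"`, `"mlp"`, `"mlp_eis"`.
#' @param gamma weight of the reconstruction error term in the objective.
#' @param delta weight of the L1 penalty on the input-scaling vector `Ue`.
#' @param use_reconstruction allocate the reconstruction path; defaults to
#'   `gamma > 0`.
#' @param detach_fat_weights if `TRUE`, gradients are not propagated through
#'   the predicted fat weights into the auxiliary networks, which are then
#'   never updated (the literal "no gradient information" reading); by
#'   default gradients flow end-to-end and only the cached fat matrices
#'   themselves are excluded from the optimizer.
#' @param reconstruction_loss `"mean"` (default) averages the squared
#'   reconstruction error over batch and features so `gamma` stays on a
#'   comparable scale to the cross-entropy at any `Nd`; `"sum"` uses the
#'   literal summed squared norm.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_features, n_hidden = 128L, n_classes = 2L,
                           aux_hidden = 256L,
                           variant = c("diet_eis", "diet", "mlp", "mlp_eis"),
                           gamma = 0, delta = 0,
                           use_reconstruction = gamma > 0,
                           detach_fat_weights = FALSE,
                           reconstruction_loss = c("mean", "sum")) {
  variant <- match.arg(variant)
  reconstruction_loss <- match.arg(reconstruction_loss)
  gamma <- check_nonneg(gamma, "gamma")
  delta <- check_nonneg(delta, "delta")
  cfg <- structure(list(
    n_features = check_count(n_features, "n_features"),
    n_hidden = check_count(n_hidden, "n_hidden"),
    n_classes = check_count(n_classes, "n_classes"),
    aux_hidden = check_count(aux_hidden, "aux_hidden"),
    variant = variant,
    gamma = gamma, delta = delta,
    use_reconstruction = isTRUE(use_reconstruction),
    detach_fat_weights = isTRUE(detach_fat_weights),
    rec_sum = reconstruction_loss == "sum"),
    class = "network_config")
  if (!cfg$use_reconstruction) cfg$gamma <- 0
  if (cfg$gamma > 0 && !cfg$use_reconstruction)
    stopf("gamma > 0 requires use_reconstruction = TRUE")
  cfg
}

is_eis <- function(config) config$variant %in% c("mlp_eis", "diet_eis")
is_diet <- function(config) config$variant %in% c("diet", "diet_eis")

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("network_config: %s  (Nd=%d, Nh=%d, Nc=%d%s)\n",
              x$variant, x$n_features, x$n_hidden, x$n_classes,
              if (is_diet(x)) sprintf(", Nj=%d", x$aux_hidden) else ""))
  cat(sprintf("  gamma=%g delta=%g reconstruction=%s detach_fat=%s\n",
              x$gamma, x$delta, x$use_reconstruction, x$detach_fat_weights))
  invisible(x)
}

# U(-1/sqrt(fan_in), 1/sqrt(fan_in)), the scaled-uniform fan-in scheme
init_affine <- function(fan_in, fan_out) {
  b <- 1 / sqrt(fan_in)
  matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out)
}

#' Initialize all learnable tensors of a model
#'
#' Affine weights and biases use a scaled-uniform fan-in scheme,
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`; the input-scaling vectors `Ue` and
#' `Ur` start at all-ones so a fresh EIS model computes exactly the same
#' forward pass as its non-EIS counterpart.
#'
#' @param config a [network_config()].
#' @param n_train width of the auxiliary networks' input, i.e. number of
#'   training samples whose transposed matrix feeds `Ge`/`Gr` (diet variants
#'   only; ignored for MLP variants).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return An object of class `model_state`: list with `params` (named list
#'   of numeric arrays, the optimizer-managed tensors), `config`, `n_train`
#'   and a `cache` slot for predicted fat weights (empty until
#'   [compute_fat_weights()]).
#' @export
initialize_state <- function(config, n_train = NULL, seed = NULL) {
  if (is_diet(config)) {
    if (is.null(n_train)) stopf("diet variants need 'n_train'")
    n_train <- check_count(n_train, "n_train")
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(check_count(seed, "seed", min = -.Machine$integer.max))
  }
  Nd <- config$n_features; Nh <- config$n_hidden; Nc <- config$n_classes
  Nj <- config$aux_hidden
  p <- list()
  if (is_diet(config)) {
    p$Ge_W1 <- init_affine(n_train, Nj); p$Ge_b1 <- numeric(Nj)
    p$Ge_W2 <- init_affine(Nj, Nh);      p$Ge_b2 <- numeric(Nh)
  } else {
    p$We <- init_affine(Nd, Nh); p$be <- numeric(Nh)
  }
  p$Wd <- init_affine(Nh, Nc); p$bd <- numeric(Nc)
  if (config$use_reconstruction) {
    if (is_diet(config)) {
      p$Gr_W1 <- init_affine(n_train, Nj); p$Gr_b1 <- numeric(Nj)
      p$Gr_W2 <- init_affine(Nj, Nh);      p$Gr_b2 <- numeric(Nh)
    } else {
      p$Wr <- init_affine(Nd, Nh); p$br <- numeric(Nd)
    }
  }
  if (is_eis(config)) {
    p$Ue <- rep(1, Nd)
    if (config$use_reconstruction) p$Ur <- rep(1, Nd)
  }
  structure(list(params = p, config = config,
                 n_train = if (is_diet(config)) n_train else NULL,
                 cache = list()),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  sizes <- vapply(x$params, length, integer(1))
  cat(sprintf("model_state: %s, %d trainable tensors, %s scalars\n",
              x$config$variant, length(sizes),
              format(sum(sizes), big.mark = ",")))
  invisible(x)
}

#' Auxiliary-network forward pass: predict a fat weight matrix
#'
#' Applies the two-layer auxiliary network (affine `n_train -> Nj`, ReLU,
#' affine `Nj -> Nh`, both with bias) independently to every row of the
#' transposed data matrix, so row `i` of the result is the predicted weight
#' vector of gene `i`, a function of that gene's pattern across the training
#' samples.
#'
#' @param XT transposed training matrix, `Nd x n_train`.
#' @param W1,b1,W2,b2 auxiliary-network parameters (shapes
#'   `n_train x Nj`, `Nj`, `Nj x Nh`, `Nh`).
#' @return The predicted fat matrix, `Nd x Nh`.
#' @export
auxiliary_forward <- function(XT, W1, b1, W2, b2) {
  if (ncol(XT) != nrow(W1))
    stopf("XT has %d columns but the auxiliary input width is %d",
          ncol(XT), nrow(W1))
  Q <- relu(sweep(XT %*% W1, 2L, b1, "+"))
  sweep(Q %*% W2, 2L, b2, "+")
}

#' Compute and cache the effective fat weight matrices
#'
#' For diet variants this runs the auxiliary networks on the (fixed)
#' transposed training matrix and stores the resulting `We` (and `Wr` when
#' the reconstruction path is on) in `state$cache`; for MLP variants it
#' simply mirrors the free parameters into the cache so downstream code has
#' one access path.
#'
#' @param state a [model_state][initialize_state()].
#' @param XT transposed training matrix (`Nd x n_train`); required for diet
#'   variants, ignored otherwise.
#' @return The state with an updated `cache` (`We`, and `Wr` if applicable).
#' @export
compute_fat_weights <- function(state, XT = NULL) {
  cfg <- state$config
  p <- state$params
  if (is_diet(cfg)) {
    if (is.null(XT)) stopf("diet variants need 'XT' to predict fat weights")
    if (nrow(XT) != cfg$n_features)
      stopf("XT has %d rows but the model expects Nd = %d",
            nrow(XT), cfg$n_features)
    state$cache$XT <- XT
    Me <- sweep(XT %*% p$Ge_W1, 2L, p$Ge_b1, "+")
    Qe <- relu(Me)
    state$cache$Ge_M <- Me
    state$cache$Ge_Q <- Qe
    state$cache$We <- sweep(Qe %*% p$Ge_W2, 2L, p$Ge_b2, "+")
    if (cfg$use_reconstruction) {
      Mr <- sweep(XT %*% p$Gr_W1, 2L, p$Gr_b1, "+")
      Qr <- relu(Mr)
      state$cache$Gr_M <- Mr
      state$cache$Gr_Q <- Qr
      state$cache$Wr <- sweep(Qr %*% p$Gr_W2, 2L, p$Gr_b2, "+")
    }
  } else {
    state$cache$We <- p$We
    if (cfg$use_reconstruction) state$cache$Wr <- p$Wr
  }
  state
}

#' Forward pass of the basic network
#'
#' Computes hidden activations, class probabilities and (when the
#' reconstruction path is on) the reconstructed input for a batch:
#' `H = relu(X Ue We [+ be])`, `Yhat = softmax(H Wd + bd)`,
#' `Xhat = sigmoid(H Wr' Ur [+ br])`, where the `Ue`/`Ur` scalings exist
#' only for EIS variants and the encoder/reconstruction biases only for MLP
#' variants.
#'
#' @param X batch matrix `B x Nd` (binary).
#' @param state a [model_state][initialize_state()] whose fat weights have
#'   been cached with [compute_fat_weights()].
#' @param config a [network_config()] (defaults to the state's own).
#' @return A list with `H` (`B x Nh`), `Y_hat` (`B x Nc`, rows sum to 1) and
#'   `X_hat` (`B x Nd` or `NULL`).
#' @export
net_forward <- function(X, state, config = state$config) {
  fw <- forward_full(X, state, config)
  list(H = fw$H, Y_hat = fw$P, X_hat = fw$Xh)
}

# internal forward keeping pre-activations for backprop
forward_full <- function(X, state, config = state$config) {
  p <- state$params
  We <- state$cache$We
  if (is.null(We)) stopf("fat weights not cached; call compute_fat_weights()")
  if (ncol(X) != config$n_features)
    stopf("X has %d columns but the model expects Nd = %d",
          ncol(X), config$n_features)
  S <- if (is_eis(config)) scale_cols(X, p$Ue) else X
  A <- S %*% We
  if (!is_diet(config)) A <- sweep(A, 2L, p$be, "+")
  H <- relu(A)
  Z <- sweep(H %*% p$Wd, 2L, p$bd, "+")
  P <- row_softmax(Z)
  out <- list(S = S, A = A, H = H, Z = Z, P = P, Xh = NULL, R0 = NULL)
  if (config$use_reconstruction) {
    Wr <- state$cache$Wr
    R0 <- tcrossprod(H, Wr)                      # B x Nd
    R1 <- if (is_eis(config)) scale_cols(R0, p$Ur) else R0
    if (!is_diet(config)) R1 <- sweep(R1, 2L, p$br, "+")
    out$R0 <- R0
    out$Xh <- sigmoid(R1)
  }
  out
}

#' Count the independently optimized scalars of an architecture
#'
#' Cached fat matrices predicted by the auxiliary networks are outputs, not
#' parameters, and are never counted; the auxiliary networks' own weights
#' are.  The MLP encoder carries a hidden bias, the diet encoder does not;
#' the reconstruction path (when enabled) mirrors the encoder's convention.
#'
#' @param config a [network_config()].
#' @param n_train training-fold size feeding the auxiliary networks (diet
#'   variants only).
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(config, n_train = NULL) {
  Nd <- config$n_features; Nh <- config$n_hidden; Nc <- config$n_classes
  Nj <- config$aux_hidden
  n <- 0
  if (is_diet(config)) {
    if (is.null(n_train)) stopf("diet variants need 'n_train'")
    n <- n + (n_train * Nj + Nj) + (Nj * Nh + Nh)     # Ge
  } else {
    n <- n + Nd * Nh + Nh                             # We + encoder bias
  }
  n <- n + Nh * Nc + Nc                               # classifier head
  if (config$use_reconstruction) {
    if (is_diet(config)) n <- n + (n_train * Nj + Nj) + (Nj * Nh + Nh)  # Gr
    else n <- n + Nd * Nh + Nd                        # Wr + output bias
  }
  if (is_eis(config)) {
    n <- n + Nd                                       # Ue
    if (config$use_reconstruction) n <- n + Nd        # Ur
  }
  as.integer(n)
}

# loss + gradients for one batch; y is 0-based class index vector.
# Returns list(loss, ce, rec, l1, grads) with grads named like params.
backward_step <- function(X, y, state, config = state$config) {
  p <- state$params
  fw <- forward_full(X, state, config)
  B <- nrow(X); Nd <- ncol(X)
  idx <- cbind(seq_len(B), y + 1L)
  logP <- fw$Z - row_logsumexp(fw$Z)
  ce <- -mean(logP[idx])
  rec <- 0; l1 <- 0
  g <- list()

  Yone <- matrix(0, B, config$n_classes)
  Yone[idx] <- 1
  dZ <- (fw$P - Yone) / B
  g$Wd <- crossprod(fw$H, dZ)
  g$bd <- colSums(dZ)
  dH <- tcrossprod(dZ, p$Wd)

  dWr_eff <- NULL
  if (config$use_reconstruction) {
    Xh <- fw$Xh
    rec <- if (isTRUE(config$rec_sum)) sum((Xh - X)^2) else mean((Xh - X)^2)
    scale <- if (isTRUE(config$rec_sum)) 1 else 1 / (B * Nd)
    dXh <- config$gamma * 2 * (Xh - X) * scale
    dR1 <- dXh * Xh * (1 - Xh)
    if (!is_diet(config)) g$br <- colSums(dR1)
    if (is_eis(config)) {
      g$Ur <- colSums(dR1 * fw$R0)
      dR0 <- scale_cols(dR1, p$Ur)
    } else dR0 <- dR1
    dWr_eff <- crossprod(dR0, fw$H)                  # Nd x Nh
    dH <- dH + dR0 %*% state$cache$Wr
  }

  dA <- dH * (fw$A > 0)
  dWe_eff <- crossprod(fw$S, dA)                     # Nd x Nh
  if (!is_diet(config)) {
    g$We <- dWe_eff
    g$be <- colSums(dA)
    if (config$use_reconstruction) g$Wr <- dWr_eff
  }
  if (is_eis(config)) {
    dS <- tcrossprod(dA, state$cache$We)
    l1 <- sum(abs(p$Ue))
    g$Ue <- colSums(dS * X) + config$delta * sign(p$Ue)
  }
  if (is_diet(config) && !config$detach_fat_weights) {
    XT <- state$cache$XT
    if (is.null(XT)) stopf("diet backward needs state$cache$XT")
    # cached aux pre-activations from compute_fat_weights (XT is fixed)
    aux_grads <- function(dW_eff, M, Q, W2) {
      dQ <- dW_eff %*% t(W2)
      dM <- dQ * (M > 0)
      list(W1 = crossprod(XT, dM), b1 = colSums(dM),
           W2 = crossprod(Q, dW_eff), b2 = colSums(dW_eff))
    }
    ag <- aux_grads(dWe_eff, state$cache$Ge_M, state$cache$Ge_Q, p$Ge_W2)
    g$Ge_W1 <- ag$W1; g$Ge_b1 <- ag$b1; g$Ge_W2 <- ag$W2; g$Ge_b2 <- ag$b2
    if (config$use_reconstruction) {
      ag <- aux_grads(dWr_eff, state$cache$Gr_M, state$cache$Gr_Q, p$Gr_W2)
      g$Gr_W1 <- ag$W1; g$Gr_b1 <- ag$b1; g$Gr_W2 <- ag$W2; g$Gr_b2 <- ag$b2
    }
  }
  list(loss = ce + config$gamma * rec + config$delta * l1,
       ce = ce, rec = rec, l1 = l1, grads = g)
}
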