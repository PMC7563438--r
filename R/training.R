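#' Optimization configuration
#'
#' Defaults follow the published training protocol: Adam with initial
#' learning rate `5e-3`, weight decay `5e-4`, mini-batches of 100 samples,
#' and an accuracy summary window of epochs 400--500 (with a 5000-epoch
#' budget).  Desk-scale runs shrink `max_epochs` and the window, not the
#' optimizer settings.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 coefficient added to every gradient (coupled
#'   weight decay, as in the reference optimizer); applied uniformly to all
#'   trainable tensors including the input-scaling vector.
#' @param batch_size mini-batch size; the final partial batch of an epoch is
#'   kept.
#' @param max_epochs number of training epochs; the per-epoch validation
#'   accuracy trace has exactly this length.
#' @param eval_window integer vector `c(first, last)` of epochs pooled by
#'   [summarize_window()].
#' @param seed base seed; fold `f` of a cross-validation derives its own
#'   stream as `seed + f - 1`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-3, weight_decay = 5e-4,
                         batch_size = 100L, max_epochs = 5000L,
                         eval_window = c(400L, 500L), seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate < 0)
    stopf("'learning_rate' must be >= 0")
  weight_decay <- check_nonneg(weight_decay, "weight_decay")
  batch_size <- check_count(batch_size, "batch_size")
  max_epochs <- check_count(max_epochs, "max_epochs")
  if (length(eval_window) != 2L || eval_window[1] > eval_window[2] ||
      eval_window[1] < 1L || eval_window[2] > max_epochs)
    stopf("'eval_window' must be c(first, last) within [1, max_epochs]")
  structure(list(learning_rate = as.numeric(learning_rate),
                 weight_decay = weight_decay,
                 batch_size = batch_size, max_epochs = max_epochs,
                 eval_window = as.integer(eval_window),
                 seed = check_count(seed, "seed", min = -.Machine$integer.max)),
            class = "train_config")
}

#' Training objective
#'
#' `L = H(Yhat, Y) + gamma * ||Xhat - X||^2 + delta * ||Ue||_1`, where the
#' cross-entropy `H` is averaged over the batch, the reconstruction error is
#' (by default) the element-wise mean of squared differences, and the L1
#' term is the sum of absolute input scales.  With `gamma = delta = 0` this
#' reduces exactly to the mean cross-entropy.
#'
#' @param Y_hat class-probability matrix, `B x Nc` (rows sum to 1).
#' @param Y integer vector of 0-based true class indices, length `B`.
#' @param X_hat,X reconstruction and target matrices (`B x Nd`); required
#'   when `gamma > 0`.
#' @param Ue input-scaling vector; required when `delta > 0`.
#' @param gamma,delta term weights.
#' @param reconstruction_loss `"mean"` (default) or `"sum"`; see
#'   [network_config()].
#' @return Scalar loss.
#' @export
objective <- function(Y_hat, Y, X_hat = NULL, X = NULL, Ue = NULL,
                      gamma = 0, delta = 0,
                      reconstruction_loss = c("mean", "sum")) {
  reconstruction_loss <- match.arg(reconstruction_loss)
  B <- nrow(Y_hat)
  idx <- cbind(seq_len(B), as.integer(Y) + 1L)
  ce <- -mean(log(Y_hat[idx]))
  loss <- ce
  if (gamma > 0) {
    if (is.null(X_hat) || is.null(X))
      stopf("gamma > 0 requires reconstruction outputs X_hat and targets X")
    rec <- if (reconstruction_loss == "sum") sum((X_hat - X)^2)
           else mean((X_hat - X)^2)
    loss <- loss + gamma * rec
  }
  if (delta > 0) {
    if (is.null(Ue)) stopf("delta > 0 requires the input-scaling vector Ue")
    loss <- loss + delta * sum(abs(Ue))
  }
  loss
}

# ---- Adam optimizer (coupled weight decay, as in the reference library) ----

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# updates only the params that received a gradient
adam_step <- function(params, grads, opt, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

#' Predict class indices for a batch
#'
#' Runs the forward pass and returns the arg-max class per sample, ties
#' broken toward the lower class index.
#'
#' @param state a [model_state][initialize_state()] with cached fat weights.
#' @param X input matrix `B x Nd`.
#' @return Integer vector of 0-based predicted class indices.
#' @export
predict_classes <- function(state, X) {
  fw <- net_forward(X, state)
  row_argmax(fw$Y_hat) - 1L
}

validation_accuracy <- function(state, Xval, yval) {
  mean(predict_classes(state, Xval) == yval)
}

#' Train one cross-validation fold
#'
#' Takes fold `fold` as the validation set and the remaining folds as the
#' training set, initializes a fresh model from the fold's derived seed,
#' and optimizes the [objective()] with Adam over shuffled mini-batches.
#' For diet variants the transposed training matrix is built once from the
#' fold's training samples and held fixed.  After every epoch the validation
#' accuracy (fraction of correct arg-max predictions) is recorded.
#'
#' @param m a [mutation_matrix()].
#' @param split a [make_cv_splits()] result over `m`.
#' @param fold fold index in `1..k` to hold out.
#' @param net_config a [network_config()].
#' @param tr_config a [train_config()].
#' @param verbose emit one `message()` per epoch with the loss components
#'   and validation accuracy.
#' @return An object of class `fold_fit`: list with `state` (trained, fat
#'   weights cached), `accuracy` (length `max_epochs`), `loss` (per-epoch
#'   mean training loss), `loss_components` (data.frame: ce, rec, l1),
#'   `fold`, `train_idx`, `val_idx`.
#' @export
train_fold <- function(m, split, fold, net_config, tr_config,
                       verbose = FALSE) {
  if (!inherits(split, "cv_split")) stopf("'split' must be a cv_split")
  fold <- check_count(fold, "fold")
  if (fold > split$k) stopf("fold %d out of range 1..%d", fold, split$k)
  val_idx <- which(split$fold == fold)
  train_idx <- which(split$fold != fold)
  if (!length(train_idx)) stopf("training fold is empty")
  Xtr <- m$X[train_idx, , drop = FALSE]
  ytr <- m$labels[train_idx]
  Xval <- m$X[val_idx, , drop = FALSE]
  yval <- m$labels[val_idx]
  storage.mode(Xtr) <- "double"
  storage.mode(Xval) <- "double"

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(tr_config$seed + fold - 1L)

  state <- initialize_state(net_config, n_train = nrow(Xtr), seed = NULL)
  XT <- if (is_diet(net_config)) t(Xtr) else NULL
  state <- compute_fat_weights(state, XT)
  opt <- adam_new(state$params)

  n_tr <- nrow(Xtr)
  bs <- tr_config$batch_size
  acc <- numeric(tr_config$max_epochs)
  loss_tr <- numeric(tr_config$max_epochs)
  comp <- matrix(0, tr_config$max_epochs, 3L,
                 dimnames = list(NULL, c("ce", "rec", "l1")))
  for (epoch in seq_len(tr_config$max_epochs)) {
    perm <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = bs)
    ep_loss <- 0; ep_ce <- 0; ep_rec <- 0; ep_l1 <- 0
    for (s in starts) {
      rows <- perm[s:min(s + bs - 1L, n_tr)]
      bw <- backward_step(Xtr[rows, , drop = FALSE], ytr[rows], state)
      upd <- adam_step(state$params, bw$grads, opt,
                       tr_config$learning_rate, tr_config$weight_decay)
      state$params <- upd$params
      opt <- upd$opt
      state <- compute_fat_weights(state, XT)
      w <- length(rows) / n_tr
      ep_loss <- ep_loss + w * bw$loss
      ep_ce <- ep_ce + w * bw$ce
      ep_rec <- ep_rec + w * bw$rec
      ep_l1 <- ep_l1 + w * bw$l1
    }
    loss_tr[epoch] <- ep_loss
    comp[epoch, ] <- c(ep_ce, ep_rec, ep_l1)
    acc[epoch] <- validation_accuracy(state, Xval, yval)
    if (verbose)
      message(sprintf(
        "fold %d epoch %d loss %.5f (ce %.5f rec %.5f l1 %.3f) val_acc %.4f",
        fold, epoch, ep_loss, ep_ce, ep_rec, ep_l1, acc[epoch]))
  }
  structure(list(state = state, accuracy = acc, loss = loss_tr,
                 loss_components = as.data.frame(comp), fold = fold,
                 train_idx = train_idx, val_idx = val_idx),
            class = "fold_fit")
}

#' k-fold cross-validation
#'
#' Runs [train_fold()] for every fold with a fresh model per fold (seed
#' derived as `seed + fold - 1`); for diet variants the transposed matrix is
#' rebuilt from each fold's training samples.
#'
#' @param m a [mutation_matrix()] whose sample count is divisible by `k`.
#' @param net_config a [network_config()].
#' @param tr_config a [train_config()].
#' @param k number of folds (default 5).
#' @param split optionally a precomputed [make_cv_splits()]; by default
#'   contiguous equal blocks are used.
#' @param keep_states keep each fold's trained `model_state` in the result
#'   (default `TRUE`; needed for the interpretability pipeline).
#' @return An object of class `cv_result`: list with `accuracy` (matrix
#'   `k x max_epochs`), `loss` (same shape), `fits` (list of `fold_fit` or
#'   `NULL`), `split`, `net_config`, `tr_config`.
#' @export
cross_validate <- function(m, net_config, tr_config, k = 5L, split = NULL,
                           keep_states = TRUE) {
  k <- check_count(k, "k")
  if (is.null(split)) split <- make_cv_splits(m, k)
  if (split$k != k) stopf("split has k = %d but k = %d requested", split$k, k)
  acc <- matrix(NA_real_, k, tr_config$max_epochs)
  loss <- matrix(NA_real_, k, tr_config$max_epochs)
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    fit <- train_fold(m, split, f, net_config, tr_config)
    acc[f, ] <- fit$accuracy
    loss[f, ] <- fit$loss
    fits[[f]] <- if (keep_states) fit else NULL
  }
  structure(list(accuracy = acc, loss = loss, fits = fits, split = split,
                 net_config = net_config, tr_config = tr_config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  w <- x$tr_config$eval_window
  w[2] <- min(w[2], ncol(x$accuracy))
  s <- summarize_window(x, w)
  cat(sprintf("cv_result: %s, %d folds x %d epochs\n",
              x$net_config$variant, nrow(x$accuracy), ncol(x$accuracy)))
  cat(sprintf("  accuracy over epochs %d-%d: %.3f +/- %.3f\n",
              w[1], w[2], s$mean, s$sd))
  invisible(x)
}

#' Pooled accuracy over an epoch window
#'
#' Pools every (fold, epoch) validation accuracy inside the window and
#' returns the mean and the population standard deviation, the summary
#' reported for each model configuration.  `per_fold = TRUE` instead
#' averages within folds first and reports the SD across fold means.
#'
#' @param result a [cross_validate()] result.
#' @param window integer `c(first, last)` epoch interval (defaults to the
#'   training config's `eval_window`).
#' @param per_fold alternative per-fold summary (default `FALSE`).
#' @return List with `mean`, `sd`, `n` (values pooled) and `window`.
#' @export
summarize_window <- function(result, window = result$tr_config$eval_window,
                             per_fold = FALSE) {
  window <- as.integer(window)
  if (length(window) != 2L || window[1] > window[2] ||
      window[1] < 1L || window[2] > ncol(result$accuracy))
    stopf("'window' must lie within the recorded epochs 1..%d",
          ncol(result$accuracy))
  block <- result$accuracy[, window[1]:window[2], drop = FALSE]
  if (per_fold) {
    fm <- rowMeans(block)
    mu <- mean(fm)
    sdv <- sqrt(mean((fm - mu)^2))
    n <- length(fm)
  } else {
    v <- as.vector(block)
    mu <- mean(v)
    sdv <- sqrt(mean((v - mu)^2))
    n <- length(v)
  }
  list(mean = mu, sd = sdv, n = n, window = window)
}

#' Persist a cross-validation result as CSV plus a JSON summary
#'
#' Writes a long-format CSV (`fold`, `epoch`, `accuracy`, `loss`) and a JSON
#' file echoing both configurations and the pooled window summary.
#'
#' @param result a [cross_validate()] result.
#' @param csv_path,summary_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cv_result <- function(result, csv_path, summary_path) {
  k <- nrow(result$accuracy)
  e <- ncol(result$accuracy)
  dt <- data.table::data.table(
    fold = rep(seq_len(k), each = e),
    epoch = rep(seq_len(e), times = k),
    accuracy = as.vector(t(result$accuracy)),
    loss = as.vector(t(result$loss)))
  data.table::fwrite(dt, csv_path)
  w <- result$tr_config$eval_window
  w[2] <- min(w[2], e)
  s <- summarize_window(result, w)
  jsonlite::write_json(
    list(mean_accuracy = s$mean, sd_accuracy = s$sd, window = s$window,
         n_pooled = s$n,
         net_config = unclass(result$net_config),
         train_config = unclass(result$tr_config)),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv_path, summary_path))
}
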