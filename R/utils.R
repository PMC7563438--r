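# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single probability in [0, 1]", name)
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stopf("'%s' must be a single nonnegative number", name)
  as.numeric(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# row-wise log-sum-exp, numerically stable
row_logsumexp <- function(z) {
  m <- apply(z, 1L, max)
  m + log(rowSums(exp(z - m)))
}

# softmax over rows
row_softmax <- function(z) {
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  e / rowSums(e)
}

# argmax over rows, ties broken toward the lower class index
row_argmax <- function(p) max.col(p, ties.method = "first")

# scale columns of a matrix by a vector: X %*% diag(u) without forming diag(u)
scale_cols <- function(x, u) t(t(x) * u)

sigmoid <- function(x) 1 / (1 + exp(-x))
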