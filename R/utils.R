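#' @importFrom stats rnorm runif kmeans setNames
#' @importFrom utils head read.csv read.delim write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package draw randomness through this so
# that results are reproducible and callers' streams are never disturbed.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit polynomial hash of a character scalar (FNV-style,
# modulus 2^31-1 so double arithmetic stays exact: 31 * (2^31-1) < 2^53).
string_hash <- function(s, mod = 2147483647) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% mod
  h
}

# Stable seed for a named stage/entity, derived from a global seed.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  as.integer(string_hash(key) %% 2147483629L)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Probabilities clamped away from {0,1} before any log (no log(0)).
PROB_EPS <- 1e-7
clamp_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

# log(sum(exp(x))) stabilized, for a numeric vector.
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Row-wise softmax of a matrix, log-sum-exp stabilized.
softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

l2_normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

# ---- Adam optimizer over a named list of arrays ------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

# Global-norm gradient clipping followed by one Adam update.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip_norm = 1.0) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(clip_norm) && gnorm > clip_norm && gnorm > 0) {
    grads <- lapply(grads, function(g) g * (clip_norm / gnorm))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Cosine-annealed learning rate with linear warm-up (in optimizer steps).
lr_schedule <- function(base_lr, step, total_steps, warmup = 200) {
  warm <- if (warmup > 0) min(1, step / warmup) else 1
  prog <- min(1, step / max(1, total_steps))
  base_lr * warm * 0.5 * (1 + cos(pi * prog))
}

# Glorot-uniform weight matrix.
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Sum rows of `M` into an n-row matrix by group index (vectorized scatter-add).
scatter_rows <- function(M, index, n) {
  agg <- rowsum(M, group = index)
  out <- matrix(0, n, ncol(M))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

stop_mmkge <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mmkge_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
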