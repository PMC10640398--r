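# Internal numerical helpers shared across modules.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# inverse of softplus, for initialising raw parameters at a target value
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_softmax <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

# Minimal Adam ascent over a named list of numeric arrays, keeping the best
# iterate seen (the objective is evaluated once more at the final point, so
# the returned parameters never score below the starting ones).
# `grad_fn(par)` must return list(value = <objective to MAXIMISE>,
# grads = <list matching par>). `project` is applied after each step (used to
# cap the spatial interaction strengths).
adam_best <- function(par, grad_fn, n_steps, lr = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      project = NULL) {
  if (n_steps <= 0L) return(par)
  best_par <- par
  best_val <- -Inf
  m <- lapply(par, function(p) p * 0)
  v <- lapply(par, function(p) p * 0)
  for (t in seq_len(n_steps)) {
    res <- grad_fn(par)
    if (res$value > best_val) { best_val <- res$value; best_par <- par }
    for (nm in names(par)) {
      g <- res$grads[[nm]]
      if (any(!is.finite(g))) {
        abort(sprintf("non-finite gradient for parameter block '%s'", nm),
              class = "spanr_numerical_error")
      }
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g^2
      par[[nm]] <- par[[nm]] +
        lr * (m[[nm]] / (1 - beta1^t)) / (sqrt(v[[nm]] / (1 - beta2^t)) + eps)
    }
    if (!is.null(project)) par <- project(par)
  }
  final <- grad_fn(par)
  if (final$value > best_val) best_par <- par
  best_par
}

# All randomness in the package flows through this: runs `expr` under a local
# RNG state seeded deterministically, restoring the caller's state after.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a distinct 31-bit sub-seed from a base seed and a stream label
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 100003L) * 7919L %% 2147483647L + match(
    stream,
    c("sim", "init", "fit", "noise", "corrupt", "batch", "misc")
  )
}
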