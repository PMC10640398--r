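#' Hidden Markov random field over spot labels
#'
#' A Potts-like prior on the label field: the unnormalised log joint is
#' `sum_k eta_k n_k - sum_{k<l} zeta_kl n_kl`, where `n_k` counts spots of
#' type `k` and `n_kl` counts neighbour pairs with discordant types `(k, l)`.
#' External fields `eta` set type prevalences; the strictly positive,
#' symmetric interactions `zeta` penalise label discord across edges, so
#' larger `zeta` means smoother maps.
#'
#' `hmrf_params()` builds a parameter set; `zeta` may be a scalar (shared
#' interaction) or a full K-by-K matrix of positive values. Interactions are
#' stored through a softplus reparameterisation of the upper triangle, which
#' keeps them positive and symmetric under gradient updates.
#'
#' @param K Number of types.
#' @param eta Length-K external field (default all zero). The model is
#'   invariant to shifting `eta` by a constant; [fit_hmrf()] pins `eta[1]`
#'   at 0 for identifiability.
#' @param zeta Positive scalar or K-by-K symmetric matrix of interaction
#'   strengths (default 1).
#' @return An object of class `hmrf_params` with fields `eta`, `zeta_raw`.
#' @export
hmrf_params <- function(K, eta = rep(0, K), zeta = 1) {
  stopifnot(K >= 1, length(eta) == K)
  if (length(zeta) == 1L) zeta <- matrix(zeta, K, K)
  zeta <- as.matrix(zeta)
  stopifnot(dim(zeta) == c(K, K))
  if (any(zeta[upper.tri(zeta)] <= 0)) {
    abort("interaction strengths zeta must be strictly positive",
          class = "spanr_invalid_parameter")
  }
  if (any(abs(zeta - t(zeta)) > 1e-12)) {
    abort("zeta must be symmetric", class = "spanr_invalid_parameter")
  }
  zr <- softplus_inv(zeta)
  diag(zr) <- -Inf # diagonal unused; zeta_kk plays no role
  structure(list(K = K, eta = as.numeric(eta), zeta_raw = zr),
            class = "hmrf_params")
}

#' @rdname hmrf_params
#' @param phi An `hmrf_params` object.
#' @export
hmrf_zeta <- function(phi) {
  z <- softplus(phi$zeta_raw)
  diag(z) <- 0
  z
}

#' Label field sufficient statistics
#'
#' @param z Integer labels in `1..K`.
#' @param graph A [spot_graph][build_knn_graph].
#' @param K Number of types.
#' @return List with `n_k` (type counts) and `n_kl` (symmetric K-by-K counts
#'   of discordant neighbour pairs, zero diagonal).
#' @export
label_statistics <- function(z, graph, K) {
  z <- check_labels(z, graph$n_spots, K)
  n_k <- tabulate(z, nbins = K)
  n_kl <- matrix(0L, K, K)
  e <- graph_edges(graph)
  if (nrow(e)) {
    zi <- z[e[, 1]]; zj <- z[e[, 2]]
    disc <- zi != zj
    if (any(disc)) {
      a <- pmin(zi[disc], zj[disc]); b <- pmax(zi[disc], zj[disc])
      tab <- table(factor(a, levels = 1:K), factor(b, levels = 1:K))
      n_kl <- matrix(as.integer(tab), K, K)
      n_kl <- n_kl + t(n_kl)
    }
  }
  list(n_k = n_k, n_kl = n_kl)
}

#' Unnormalised log joint of a labelling
#'
#' `sum_k eta_k n_k - sum_{k<l} zeta_kl n_kl`: at equal fields, smoother
#' labelings (fewer discordant edges) score higher.
#'
#' @inheritParams label_statistics
#' @param phi An `hmrf_params` object.
#' @export
joint_log_potential <- function(z, graph, phi) {
  st <- label_statistics(z, graph, phi$K)
  zeta <- hmrf_zeta(phi)
  sum(phi$eta * st$n_k) - sum(zeta[upper.tri(zeta)] * st$n_kl[upper.tri(st$n_kl)])
}

#' Per-spot conditional log-weights
#'
#' The full conditional of one spot's label given its neighbours' labels:
#' `logit_k = eta_k - sum_{l != k} zeta_kl u(l)` with `u(l)` the number of
#' neighbours of type `l`. Normalise with log-sum-exp to get probabilities.
#'
#' @param u Length-K neighbour type counts, or an N-by-K matrix of them.
#' @param phi An `hmrf_params` object.
#' @return Log-weights shaped like `u`.
#' @export
conditional_logits <- function(u, phi) {
  zeta <- hmrf_zeta(phi)
  if (is.matrix(u)) {
    sweep(-(u %*% zeta), 2L, phi$eta, `+`)
  } else {
    phi$eta - as.numeric(zeta %*% u)
  }
}

#' Pseudolikelihood of a labelling
#'
#' Sum over spots of the log conditional probability of the observed label
#' given the observed neighbour labels; the tractable surrogate used to
#' estimate the field parameters. Always non-positive.
#'
#' @inheritParams joint_log_potential
#' @export
pseudolikelihood <- function(z, graph, phi) {
  z <- check_labels(z, graph$n_spots, phi$K)
  u <- neighbor_type_counts(graph, z, phi$K)
  scores <- conditional_logits(u, phi)
  mx <- apply(scores, 1L, max)
  sum(scores[cbind(seq_along(z), z)] - mx - log(rowSums(exp(scores - mx))))
}

#' Estimate HMRF parameters by penalised pseudolikelihood ascent
#'
#' Adam ascent on the pseudolikelihood minus a small ridge penalty
#' `ridge * sum(zeta_raw^2)` on the raw interaction parameters. `eta[1]` is
#' held at 0 (the conditionals are invariant to shifting all fields) and the
#' interactions are capped at `zeta_max`: a perfectly smooth labelling would
#' otherwise push them to infinity, and the cap preserves the "effectively
#' infinite" smoothing while keeping the label updates numerically stable.
#'
#' @inheritParams joint_log_potential
#' @param phi_init Starting `hmrf_params` (default: zero fields, unit
#'   interactions).
#' @param n_steps Adam steps (default 50).
#' @param lr Learning rate (default 0.01).
#' @param ridge Ridge weight on raw interactions (default 1e-3).
#' @param zeta_max Interaction cap (default 20).
#' @return Fitted `hmrf_params`.
#' @export
fit_hmrf <- function(z, graph, phi_init = NULL, n_steps = 50, lr = 0.01,
                     ridge = 1e-3, zeta_max = 20) {
  if (is.null(phi_init)) {
    K <- max(z)
    phi_init <- hmrf_params(K)
  }
  K <- phi_init$K
  if (K < 2L) abort("the label field needs K >= 2 types", class = "spanr_degenerate_model")
  z <- check_labels(z, graph$n_spots, K)
  u <- neighbor_type_counts(graph, z, K)
  ind <- matrix(0, length(z), K)
  ind[cbind(seq_along(z), z)] <- 1
  up <- upper.tri(matrix(0, K, K))

  par <- list(eta_free = phi_init$eta[-1] - phi_init$eta[1],
              zeta_free = phi_init$zeta_raw[up])
  raw_cap <- softplus_inv(zeta_max)

  grad_fn <- function(par) {
    phi <- assemble_phi(par, K, up)
    scores <- conditional_logits(u, phi)
    mx <- apply(scores, 1L, max)
    lse <- mx + log(rowSums(exp(scores - mx)))
    value <- sum(scores[cbind(seq_len(nrow(u)), z)] - lse) -
      ridge * sum(par$zeta_free^2)
    p <- exp(scores - lse)
    resid <- ind - p
    g_eta <- colSums(resid)[-1]
    M <- t(resid) %*% u
    g_zeta_full <- -(M + t(M)) * stats::plogis(phi$zeta_raw)
    g_zeta <- g_zeta_full[up] - 2 * ridge * par$zeta_free
    list(value = value, grads = list(eta_free = g_eta, zeta_free = g_zeta))
  }

  project <- function(par) {
    par$zeta_free <- pmin(par$zeta_free, raw_cap)
    par
  }

  best <- adam_best(par, grad_fn, n_steps = n_steps, lr = lr, project = project)
  assemble_phi(best, K, up)
}

assemble_phi <- function(par, K, up) {
  zr <- matrix(0, K, K)
  zr[up] <- par$zeta_free
  zr <- zr + t(zr)
  diag(zr) <- -Inf
  structure(list(K = K, eta = c(0, par$eta_free), zeta_raw = zr),
            class = "hmrf_params")
}

#' @export
print.hmrf_params <- function(x, ...) {
  zeta <- hmrf_zeta(x)
  cat(sprintf("<hmrf_params> K = %d; eta = [%s]; zeta range (off-diag) = [%.3g, %.3g]\n",
              x$K, paste(sprintf("%.3g", x$eta), collapse = ", "),
              min(zeta[upper.tri(zeta)]), max(zeta[upper.tri(zeta)])))
  invisible(x)
}
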