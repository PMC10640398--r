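#' Size factors from marker counts
#'
#' Per-spot scaling absorbing sequencing-depth differences: the spot's total
#' count over the median total across spots. Scale-free (multiplying all
#' counts by a constant leaves the factors unchanged) and robust to a few
#' very deep spots.
#'
#' @param Y Spot-by-gene count matrix.
#' @return Numeric vector of strictly positive size factors, one per spot.
#' @export
compute_size_factors <- function(Y) {
  Y <- check_counts(Y)
  totals <- rowSums(Y)
  if (any(totals == 0)) {
    bad <- rownames(Y)[which(totals == 0)]
    abort(paste0("spot(s) with all-zero counts: ", paste(head(bad, 5), collapse = ", ")),
          class = "spanr_degenerate_spot")
  }
  s <- totals / median(totals)
  names(s) <- rownames(Y)
  s
}

#' Negative binomial log mass
#'
#' Mean/inverse-dispersion convention: `Var = mu + mu^2 / phi`, so `phi` is
#' the size parameter and large `phi` approaches the Poisson limit.
#'
#' @param y Non-negative integer counts.
#' @param mu Positive means.
#' @param phi Positive inverse-dispersions.
#' @return Log probability mass, vectorised over the inputs.
#' @export
nb_logpmf <- function(y, mu, phi) {
  if (any(mu <= 0) || any(phi <= 0)) {
    abort("mu and phi must be strictly positive", class = "spanr_domain_error")
  }
  if (any(y < 0) || any(y != round(y))) {
    abort("y must be non-negative integers", class = "spanr_domain_error")
  }
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    phi * log(phi / (phi + mu)) + ifelse(y > 0, y * log(mu / (phi + mu)), 0)
}

#' Mixture mean and dispersion surfaces
#'
#' `compute_log_mean()` evaluates the log-linear mean model
#' `log mu_igk = log s_i + delta_gk rho_gk + beta_g0 + sum_p beta_gp x_ip`:
#' a marker gene's mean is multiplied by `exp(delta_gk)` in the type it
#' marks, on top of its base expression and the spot's depth. The log fold
#' change `delta_gk` is a learned, strictly positive parameter.
#' `compute_dispersion()` ties the NB inverse-dispersion to the mean through
#' a radial-basis-function expansion `phi = sum_j a_j exp(-b_j (mu - x_j)^2)`
#' with fixed centres `x_j` and learned non-negative amplitudes/widths,
#' floored at `1e-6` so the mass function stays defined when the sum
#' underflows.
#'
#' @param params A `mixture_params` object.
#' @param s Size factors (length N).
#' @param X N-by-P covariate matrix (may have zero columns).
#' @param rho G-by-K binary marker indicator.
#' @param mu Array of means, any shape.
#' @return `compute_log_mean()`: an N-by-G-by-K array of log means;
#'   `compute_dispersion()`: an array of dispersions shaped like `mu`.
#' @export
compute_log_mean <- function(params, s, X, rho) {
  if (any(s <= 0)) abort("size factors must be strictly positive",
                         class = "spanr_invalid_size_factor")
  G <- length(params$beta0); K <- ncol(params$delta_raw); N <- length(s)
  X <- as_covariates(X, N)
  cov_term <- if (ncol(X) > 0) X %*% t(params$beta) else matrix(0, N, G)
  lmu <- array(0, dim = c(N, G, K))
  delta <- exp(params$delta_raw)
  for (k in seq_len(K)) {
    gk <- delta[, k] * rho[, k] + params$beta0 # length G
    lmu[, , k] <- log(s) + matrix(gk, N, G, byrow = TRUE) + cov_term
  }
  lmu
}

#' @rdname compute_log_mean
#' @export
compute_dispersion <- function(mu, params) {
  a <- softplus(params$a_raw); b <- softplus(params$b_raw)
  phi <- mu * 0
  for (j in seq_along(a)) {
    phi <- phi + a[j] * exp(-b[j] * (mu - params$centers[j])^2)
  }
  pmax(phi, 1e-6)
}

#' Mixture responsibilities (E-step)
#'
#' Posterior type probabilities per spot under the current parameters:
#' `gamma_ik` proportional to `pi_k * prod_g NB(y_ig | mu_igk, phi_igk)`,
#' computed in log space with log-sum-exp normalisation.
#'
#' @inheritParams compute_log_mean
#' @param Y Spot-by-gene count matrix (marker genes only).
#' @return N-by-K matrix of responsibilities; rows sum to one.
#' @export
e_step <- function(Y, params, s, X, rho) {
  L <- loglik_matrix(Y, params, s, X, rho)
  if (any(!is.finite(L))) {
    bad <- which(!is.finite(L), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite log-likelihood at spot %d, type %d", bad[1], bad[2]),
          class = "spanr_numerical_error")
  }
  gamma <- row_softmax(sweep(L, 2L, log(mixture_pi(params)), `+`))
  dimnames(gamma) <- list(rownames(Y), colnames(rho))
  gamma
}

#' EM objective (Q function)
#'
#' The responsibility-weighted expected complete-data log-likelihood plus the
#' MAP prior terms: a log-normal prior on the marker fold changes `delta`
#' (applied only where `rho_gk = 1`, since elsewhere `delta` is inert) and a
#' symmetric Dirichlet prior on the mixing weights `pi`.
#'
#' @inheritParams e_step
#' @param gamma N-by-K responsibility matrix.
#' @param hyper Hyper-parameters from [mixture_hyperparams()].
#' @param include_priors,include_pi Drop the prior / mixing-weight terms
#'   (used by the spatial model, whose conditional likelihood has neither).
#' @return A single finite number.
#' @export
q_objective <- function(Y, gamma, params, s, X, rho,
                        hyper = mixture_hyperparams(),
                        include_priors = TRUE, include_pi = TRUE) {
  X <- as_covariates(X, nrow(Y))
  val <- nb_weighted_loglik(Y, s, X, params$delta_raw, params$beta0, params$beta,
                            params$a_raw, params$b_raw, params$centers, rho,
                            gamma, FALSE)$value
  if (include_pi) {
    val <- val + sum(colSums(gamma) * log(mixture_pi(params)))
  }
  if (include_priors) val <- val + log_prior(params, rho, hyper, include_pi)
  val
}

log_prior <- function(params, rho, hyper, include_pi = TRUE) {
  marked <- rho == 1
  d <- params$delta_raw[marked]
  lp <- sum(-d - 0.5 * log(2 * pi * hyper$sigma2) -
              (d - hyper$delta_bar)^2 / (2 * hyper$sigma2))
  if (include_pi) {
    lp <- lp + sum((hyper$alpha - 1) * log(mixture_pi(params)))
  }
  lp
}

#' Gradient M-step
#'
#' A partial M-step: `n_steps` Adam updates on the Q function, with
#' positivity handled by reparameterisation (`delta = exp(raw)`,
#' `a, b = softplus(raw)`, `pi = softmax(raw)` floored at `1e-8`). The best
#' iterate visited is returned, so the EM objective never decreases.
#'
#' @inheritParams q_objective
#' @param n_steps Number of gradient updates (0 returns `params` unchanged).
#' @param lr Adam learning rate.
#' @param update_pi Include the mixing weights in the update (the spatial
#'   model's conditional likelihood re-uses this step without them).
#' @return Updated `mixture_params`.
#' @export
m_step <- function(Y, gamma, params, s, X, rho,
                   hyper = mixture_hyperparams(),
                   n_steps = 30, lr = 0.01,
                   include_priors = TRUE, update_pi = TRUE) {
  if (n_steps <= 0L) return(params)
  X <- as_covariates(X, nrow(Y))
  P <- ncol(X)
  marked <- rho == 1
  csum_gamma <- colSums(gamma)

  blocks <- c("delta_raw", "beta0", "a_raw", "b_raw")
  if (P > 0) blocks <- c(blocks, "beta")
  if (update_pi) blocks <- c(blocks, "pi_raw")
  par <- params[intersect(names(params), blocks)]

  grad_fn <- function(par) {
    full <- modifyList(params, par)
    res <- nb_weighted_loglik(Y, s, X, full$delta_raw, full$beta0, full$beta,
                              full$a_raw, full$b_raw, full$centers, rho,
                              gamma, TRUE)
    value <- res$value
    grads <- list(delta_raw = res$g_delta_raw, beta0 = res$g_beta0,
                  a_raw = res$g_a_raw, b_raw = res$g_b_raw)
    if (P > 0) grads$beta <- res$g_beta
    if (include_priors) {
      value <- value + log_prior(full, rho, hyper, include_pi = update_pi)
      gd_prior <- matrix(0, nrow(rho), ncol(rho))
      gd_prior[marked] <- -1 - (full$delta_raw[marked] - hyper$delta_bar) / hyper$sigma2
      grads$delta_raw <- grads$delta_raw + gd_prior
    }
    if (update_pi) {
      pk <- mixture_pi(full)
      ck <- csum_gamma + if (include_priors) (hyper$alpha - 1) else 0
      value <- value + sum(ck * log(pk))
      grads$pi_raw <- ck - sum(ck) * pk
    }
    list(value = value, grads = grads)
  }

  best <- adam_best(par, grad_fn, n_steps = n_steps, lr = lr)
  modifyList(params, best)
}

#' Fit the marker-informed NB mixture by EM
#'
#' Alternates responsibilities ([e_step()]) and partial gradient M-steps
#' ([m_step()]) until the relative change in the MAP objective falls below
#' `tol` or `max_iters` is reached. This is also the spatially unaware
#' pretraining stage of [fit_span()].
#'
#' @inheritParams q_objective
#' @param X Optional N-by-P covariate matrix (e.g. one-hot batch indicators).
#' @param control List from [mixture_control()].
#' @param seed Integer seed governing parameter initialisation.
#' @return An object of class `nb_mixture_fit`: list with `params`, `gamma`,
#'   `history` (Q per iteration), `converged`, `n_iters`.
#' @export
fit_mixture <- function(Y, rho, X = NULL,
                        hyper = mixture_hyperparams(),
                        control = mixture_control(),
                        seed = 1L) {
  Y <- check_counts(Y)
  rho <- check_markers(rho, Y)
  X <- as_covariates(X, nrow(Y))
  s <- compute_size_factors(Y)
  K <- ncol(rho)
  params <- init_mixture_params(Y, rho, X, hyper, seed)

  if (K == 1L) {
    gamma <- matrix(1, nrow(Y), 1L, dimnames = list(rownames(Y), colnames(rho)))
    return(structure(list(params = params, gamma = gamma, s = s,
                          history = numeric(0), converged = TRUE, n_iters = 0L),
                     class = "nb_mixture_fit"))
  }

  history <- numeric(0)
  q_prev <- -Inf
  converged <- FALSE
  stall <- 0L
  for (it in seq_len(control$max_iters)) {
    gamma <- e_step(Y, params, s, X, rho)
    params <- m_step(Y, gamma, params, s, X, rho, hyper,
                     n_steps = control$n_grad_steps, lr = control$lr,
                     update_pi = control$estimate_pi)
    q <- q_objective(Y, gamma, params, s, X, rho, hyper)
    history <- c(history, q)
    if (is.finite(q_prev)) {
      if (q < q_prev + 1e-8) stall <- stall + 1L else stall <- 0L
      if (abs(q - q_prev) < control$tol * abs(q_prev)) {
        converged <- TRUE
        q_prev <- q
        break
      }
      if (stall >= 5L) {
        warn("EM objective failed to improve for 5 consecutive iterations; stopping")
        converged <- TRUE
        q_prev <- q
        break
      }
    }
    q_prev <- q
  }
  gamma <- e_step(Y, params, s, X, rho)
  structure(list(params = params, gamma = gamma, s = s, history = history,
                 converged = converged, n_iters = length(history)),
            class = "nb_mixture_fit")
}

#' Mixture hyper-parameters and EM control settings
#'
#' `delta_bar`/`sigma2` are the mean and variance of the log-normal prior on
#' marker fold changes; `alpha` the symmetric Dirichlet concentration on the
#' mixing weights; `B` the number of RBF centres of the mean-dispersion
#' curve, equally spaced from 0 to the maximum observed count.
#'
#' @param delta_bar,sigma2 Log-normal prior location/variance (defaults 0, 1).
#' @param alpha Dirichlet concentration (default 0.01).
#' @param B Number of RBF centres (default 10).
#' @export
mixture_hyperparams <- function(delta_bar = 0, sigma2 = 1, alpha = 0.01, B = 10L) {
  stopifnot(sigma2 > 0, alpha > 0, B >= 1)
  list(delta_bar = delta_bar, sigma2 = sigma2, alpha = alpha, B = as.integer(B))
}

#' @rdname mixture_hyperparams
#' @param tol Relative Q-change convergence tolerance.
#' @param max_iters Maximum EM iterations.
#' @param n_grad_steps Adam updates per M-step.
#' @param lr Adam learning rate.
#' @param estimate_pi Update the mixing weights during EM. Off by default:
#'   with the sparse Dirichlet prior (`alpha` < 1) and the diffuse
#'   responsibilities of early iterations, estimated weights feed a
#'   rich-get-richer loop that can empty weakly separated components, so the
#'   weights stay at their uniform initialisation unless requested.
#' @export
mixture_control <- function(tol = 1e-4, max_iters = 50L, n_grad_steps = 30L, lr = 0.01,
                            estimate_pi = FALSE) {
  list(tol = tol, max_iters = as.integer(max_iters),
       n_grad_steps = as.integer(n_grad_steps), lr = lr,
       estimate_pi = isTRUE(estimate_pi))
}

# Moment-based initialisation. Each marker's fold change is seeded from a
# quantile split of its depth-normalised expression: the mean over the top
# N/K spots (the expected size of the marked group) against the mean over the
# rest. Base expression starts at the log rest-mean. Random fold-change
# initialisation leaves the EM prone to self-consistent wrong labelings on
# weakly separated data; the moment seed lands in the right basin.
init_mixture_params <- function(Y, rho, X, hyper, seed) {
  G <- ncol(Y); K <- ncol(rho); P <- ncol(X); B <- hyper$B
  ymax <- max(Y, 1)
  centers <- seq(0, ymax, length.out = B)
  dx <- if (B > 1) centers[2] - centers[1] else ymax

  s <- rowSums(Y) / median(rowSums(Y))
  e <- Y / s
  ntop <- max(3L, round(nrow(Y) / K))
  delta_raw <- matrix(log(0.5), G, K)
  beta0 <- numeric(G)
  for (g in seq_len(G)) {
    x <- sort(e[, g], decreasing = TRUE)
    top <- mean(x[seq_len(ntop)])
    rest <- mean(x[-seq_len(ntop)])
    beta0[g] <- log(max(rest, 0.01))
    d <- log(max(top, 0.02) / max(rest, 0.01))
    delta_raw[g, rho[g, ] == 1] <- log(min(max(d, 0.1), 3))
  }
  structure(
    list(delta_raw = delta_raw,
         beta0 = beta0,
         beta = matrix(0, G, P),
         a_raw = rep(softplus_inv(1), B),
         b_raw = rep(softplus_inv(1 / (2 * dx^2)), B),
         centers = centers,
         pi_raw = rep(0, K),
         type_names = colnames(rho), gene_names = colnames(Y)),
    class = "mixture_params")
}

#' Mixing weights of a mixture parameter set
#'
#' Softmax of the raw weights, floored at `1e-8` and renormalised (the
#' Dirichlet concentration below 1 would otherwise allow degenerate zeros).
#' @param params A `mixture_params` object.
#' @export
mixture_pi <- function(params) {
  p <- exp(params$pi_raw - max(params$pi_raw))
  p <- p / sum(p)
  p <- pmax(p, 1e-8)
  p / sum(p)
}

loglik_matrix <- function(Y, params, s, X, rho) {
  X <- as_covariates(X, nrow(Y))
  nb_loglik_matrix(Y, s, X, params$delta_raw, params$beta0, params$beta,
                   params$a_raw, params$b_raw, params$centers, rho)
}

check_counts <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0) || any(Y != round(Y))) {
    abort("counts must be non-negative integers", class = "spanr_invalid_input")
  }
  if (is.null(rownames(Y))) rownames(Y) <- paste0("spot", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("gene", seq_len(ncol(Y)))
  storage.mode(Y) <- "double"
  Y
}

check_markers <- function(rho, Y) {
  rho <- as.matrix(rho)
  if (!all(rho %in% c(0, 1))) {
    abort("marker matrix must be binary", class = "spanr_invalid_input")
  }
  if (nrow(rho) != ncol(Y)) {
    abort("marker matrix rows must match count matrix genes",
          class = "spanr_invalid_input")
  }
  if (any(rowSums(rho) == 0)) {
    abort("every gene must mark at least one type (drop uninformative genes first)",
          class = "spanr_invalid_input")
  }
  if (any(colSums(rho) == 0)) {
    abort("every type must have at least one marker gene",
          class = "spanr_invalid_input")
  }
  if (is.null(colnames(rho))) colnames(rho) <- paste0("type", seq_len(ncol(rho)))
  if (is.null(rownames(rho))) rownames(rho) <- colnames(Y)
  storage.mode(rho) <- "double"
  rho
}

as_covariates <- function(X, N) {
  if (is.null(X)) return(matrix(0, N, 0))
  X <- as.matrix(X)
  if (nrow(X) != N) abort("covariate rows must match spots", class = "spanr_invalid_input")
  if (any(!is.finite(X))) abort("covariates must be finite", class = "spanr_invalid_input")
  storage.mode(X) <- "double"
  X
}

#' @export
print.nb_mixture_fit <- function(x, ...) {
  cat(sprintf("<nb_mixture_fit> %d spots x %d genes, K = %d; %d EM iterations (%s)\n",
              nrow(x$gamma), length(x$params$beta0), ncol(x$gamma), x$n_iters,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
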