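#' SPAN fitting configuration
#'
#' Defaults follow the method's reference settings: Adam learning rate 0.01,
#' 10 RBF centres, stop when fewer than 0.1% of labels change in an ICM
#' iteration, at most 20 ICM iterations, 30 gradient steps per mixture
#' update and 50 per field update.
#'
#' @param learning_rate Adam learning rate for all gradient updates.
#' @param B Number of RBF centres of the dispersion curve.
#' @param max_icm_iters Maximum outer ICM iterations.
#' @param label_change_tol Stop when the fraction of spots changing label in
#'   a sweep is at or below this (default 0.001).
#' @param n_grad_steps_gamma Gradient steps per mixture (Gamma) update.
#' @param n_grad_steps_phi Gradient steps per field (Phi) update.
#' @param pretrain_tol,pretrain_max_iters EM settings for the spatially
#'   unaware pretraining stage.
#' @param spatial Set `FALSE` to force the interactions `zeta` to zero
#'   throughout: the spatially blind ablation, equivalent to per-spot
#'   maximum-likelihood labels under the mixture.
#' @param seed Integer seed; the whole fit is deterministic given it.
#' @export
span_config <- function(learning_rate = 0.01, B = 10L,
                        max_icm_iters = 20L, label_change_tol = 0.001,
                        n_grad_steps_gamma = 30L, n_grad_steps_phi = 50L,
                        pretrain_tol = 1e-4, pretrain_max_iters = 50L,
                        spatial = TRUE, seed = 1L) {
  stopifnot(label_change_tol > 0, label_change_tol < 1,
            max_icm_iters >= 0, learning_rate > 0)
  list(learning_rate = learning_rate, B = as.integer(B),
       max_icm_iters = as.integer(max_icm_iters),
       label_change_tol = label_change_tol,
       n_grad_steps_gamma = as.integer(n_grad_steps_gamma),
       n_grad_steps_phi = as.integer(n_grad_steps_phi),
       pretrain_tol = pretrain_tol,
       pretrain_max_iters = as.integer(pretrain_max_iters),
       spatial = isTRUE(spatial), seed = as.integer(seed))
}

#' Conditional data log-likelihood of a hard labelling
#'
#' `L2 = sum_i sum_g log NB(y_ig | mu_{ig z_i}, phi_{ig z_i})`: the mixture
#' log-likelihood with the latent types fixed at `z`. Equals the
#' responsibility-weighted data term of [q_objective()] when the
#' responsibilities one-hot encode `z` (no mixing-weight or prior terms).
#'
#' @inheritParams e_step
#' @param z Integer labels in `1..K`.
#' @export
conditional_log_likelihood <- function(Y, z, params, s, X, rho) {
  L <- loglik_matrix(Y, params, s, X, rho)
  z <- check_labels(z, nrow(Y), ncol(rho))
  sum(L[cbind(seq_along(z), z)])
}

#' One ICM label sweep
#'
#' Visits spots in ascending index order; each spot is set to the type
#' maximising its data log-likelihood plus the spatial conditional
#' log-weight given the neighbours' *current* labels (already-updated labels
#' propagate within the sweep). Ties go to the smallest type index. The
#' reported posterior is the softmax of each spot's score vector at visit
#' time.
#'
#' @inheritParams conditional_log_likelihood
#' @param graph A [spot_graph][build_knn_graph].
#' @param phi An `hmrf_params` object.
#' @return List with `z` (updated labels), `posterior` (N-by-K), and
#'   `changed_fraction`.
#' @export
icm_sweep <- function(Y, z, graph, params, phi, s, X, rho) {
  K <- ncol(rho)
  L <- loglik_matrix(Y, params, s, X, rho)
  z <- check_labels(z, nrow(Y), K)
  zeta <- hmrf_zeta(phi)
  eta <- phi$eta
  z_new <- z
  post <- matrix(0, nrow(Y), K)
  for (i in seq_len(graph$n_spots)) {
    nb <- graph$adjacency[[i]]
    u <- if (length(nb)) tabulate(z_new[nb], nbins = K) else numeric(K)
    score <- L[i, ] + eta - as.numeric(zeta %*% u)
    z_new[i] <- which.max(score) # which.max takes the smallest index on ties
    post[i, ] <- exp(score - logsumexp(score))
  }
  dimnames(post) <- list(rownames(Y), colnames(rho))
  list(z = z_new, posterior = post,
       changed_fraction = mean(z_new != z))
}

#' Fit the SPAN model
#'
#' The full marker-informed spatial assignment procedure:
#' 1. pretrain the NB mixture without spatial information ([fit_mixture()])
#'    and initialise labels at the responsibility argmax;
#' 2. iterate: update the mixture parameters Gamma by gradient ascent on the
#'    conditional likelihood of the current hard labels (plus the MAP
#'    priors), re-estimate the field parameters Phi by penalised
#'    pseudolikelihood ([fit_hmrf()]), and run one ICM label sweep;
#' 3. stop when the fraction of labels changed in a sweep is at or below
#'    `label_change_tol`, or after `max_icm_iters` iterations.
#'
#' The mixing weights `pi` act only during pretraining; the final posterior
#' combines data likelihood and spatial conditional only.
#'
#' @param Y Spot-by-gene count matrix restricted to marker genes.
#' @param rho G-by-K binary marker indicator (column names = type names).
#' @param graph A [spot_graph][build_knn_graph] over the spots.
#' @param X Optional N-by-P covariate matrix.
#' @param config A [span_config()].
#' @param hyper A [mixture_hyperparams()].
#' @param pretrain Optional precomputed [fit_mixture()] result for this exact
#'   `Y`/`rho`/`X` and `config$seed`, to warm-start (e.g. when fitting the
#'   full model and its spatially blind ablation on the same data). When
#'   omitted the mixture is pretrained internally.
#' @return An object of class `span_fit`: `z` (integer labels), `type` (type
#'   names), `posterior`, `mixture_params`, `hmrf_params`, `history` (tibble
#'   with per-iteration label-change fraction, conditional likelihood and
#'   pseudolikelihood), `converged`, plus the pretraining fit.
#' @export
fit_span <- function(Y, rho, graph, X = NULL, config = span_config(),
                     hyper = mixture_hyperparams(B = config$B),
                     pretrain = NULL) {
  Y <- check_counts(Y)
  rho <- check_markers(rho, Y)
  K <- ncol(rho)
  if (K < 2L) abort("SPAN needs K >= 2 types", class = "spanr_degenerate_model")
  if (graph$n_spots != nrow(Y)) {
    abort("graph and count matrix disagree on the number of spots",
          class = "spanr_invalid_input")
  }
  X <- as_covariates(X, nrow(Y))

  pre <- pretrain
  if (is.null(pre)) {
    pre <- fit_mixture(Y, rho, X, hyper = hyper,
                       control = mixture_control(tol = config$pretrain_tol,
                                                 max_iters = config$pretrain_max_iters,
                                                 n_grad_steps = config$n_grad_steps_gamma,
                                                 lr = config$learning_rate),
                       seed = config$seed)
  } else if (!inherits(pre, "nb_mixture_fit") || nrow(pre$gamma) != nrow(Y)) {
    abort("pretrain must be an nb_mixture_fit for the same data",
          class = "spanr_invalid_input")
  }
  s <- pre$s
  params <- pre$params
  z <- max.col(pre$gamma, ties.method = "first")
  posterior <- pre$gamma
  phi <- hmrf_params(K)
  if (!config$spatial) phi <- zero_field(K)

  history <- list()
  converged <- FALSE
  for (t in seq_len(config$max_icm_iters)) {
    # Gamma update: conditional likelihood of the current hard labels + priors
    onehot <- matrix(0, nrow(Y), K)
    onehot[cbind(seq_along(z), z)] <- 1
    params <- m_step(Y, onehot, params, s, X, rho, hyper,
                     n_steps = config$n_grad_steps_gamma,
                     lr = config$learning_rate, update_pi = FALSE)
    # Phi update by pseudolikelihood (skipped for the spatially blind ablation)
    if (config$spatial) {
      phi <- fit_hmrf(z, graph, phi_init = phi,
                      n_steps = config$n_grad_steps_phi,
                      lr = config$learning_rate)
    }
    sw <- icm_sweep(Y, z, graph, params, phi, s, X, rho)
    if (config$spatial && any(tabulate(sw$z, K) == 0L)) {
      warn(sprintf("type(s) %s empty after ICM iteration %d; retained",
                   paste(which(tabulate(sw$z, K) == 0L), collapse = ","), t))
    }
    z <- sw$z
    posterior <- sw$posterior
    history[[t]] <- tibble::tibble(
      iter = t, changed_fraction = sw$changed_fraction,
      conditional_loglik = conditional_log_likelihood(Y, z, params, s, X, rho),
      pseudolikelihood = if (config$spatial) pseudolikelihood(z, graph, phi) else NA_real_)
    if (sw$changed_fraction <= config$label_change_tol) {
      converged <- TRUE
      break
    }
  }
  if (config$max_icm_iters == 0L) converged <- TRUE

  structure(
    list(z = z, type = colnames(rho)[z], posterior = posterior,
         mixture_params = params, hmrf_params = phi,
         history = if (length(history)) dplyr::bind_rows(history) else
           tibble::tibble(iter = integer(), changed_fraction = numeric(),
                          conditional_loglik = numeric(), pseudolikelihood = numeric()),
         converged = converged, pretrain = pre, s = s,
         spot_ids = rownames(Y), type_names = colnames(rho),
         config = config),
    class = "span_fit")
}

# eta = 0, zeta -> 0: the spatial term vanishes from every conditional
zero_field <- function(K) {
  phi <- hmrf_params(K, zeta = 1e-12)
  phi
}

#' @export
print.span_fit <- function(x, ...) {
  cat(sprintf("<span_fit> %d spots, K = %d; %d ICM iteration(s), %s\n",
              length(x$z), length(x$type_names), nrow(x$history),
              if (x$converged) "converged" else "not converged"))
  tab <- table(factor(x$type, levels = x$type_names))
  cat("  assignment counts: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a SPAN fit
#'
#' `tidy()` returns one row per spot with the assigned type and its posterior
#' probability; `glance()` a one-row model summary.
#'
#' @param x A `span_fit`.
#' @param ... Unused.
#' @method tidy span_fit
#' @export
tidy.span_fit <- function(x, ...) {
  tibble::tibble(
    spot_id = x$spot_ids,
    type = x$type,
    posterior = x$posterior[cbind(seq_along(x$z), x$z)])
}

#' @rdname tidy.span_fit
#' @method glance span_fit
#' @export
glance.span_fit <- function(x, ...) {
  tibble::tibble(
    n_spots = length(x$z),
    n_types = length(x$type_names),
    n_icm_iters = nrow(x$history),
    converged = x$converged,
    final_label_change = if (nrow(x$history)) x$history$changed_fraction[nrow(x$history)] else 0,
    conditional_loglik = if (nrow(x$history)) x$history$conditional_loglik[nrow(x$history)] else NA_real_)
}
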