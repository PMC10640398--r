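# Small fixtures and independent oracles shared across tests.

softplus_inv_t <- function(y) spanr:::softplus_inv(y)

# Graph from an explicit edge list (1-based), for hand-checkable cases.
graph_from_edges <- function(n, edges) {
  adj <- rep(list(integer(0)), n)
  for (e in edges) {
    adj[[e[1]]] <- sort(unique(c(adj[[e[1]]], e[2])))
    adj[[e[2]]] <- sort(unique(c(adj[[e[2]]], e[1])))
  }
  spanr:::new_spot_graph(adj, as.character(seq_len(n)))
}

path_graph <- function(n) {
  graph_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

# Independent NB mixture pieces built on dnbinom (mean/size parameterisation
# matches the package's Var = mu + mu^2/phi convention).
oracle_mu <- function(params, s, X, rho, i, g, k) {
  exp(log(s[i]) + exp(params$delta_raw[g, k]) * rho[g, k] + params$beta0[g] +
        (if (ncol(X) > 0) sum(params$beta[g, ] * X[i, ]) else 0))
}

oracle_phi <- function(mu, params) {
  a <- spanr:::softplus(params$a_raw); b <- spanr:::softplus(params$b_raw)
  max(sum(a * exp(-b * (mu - params$centers)^2)), 1e-6)
}

# Brute-force Bayes-rule responsibilities on a tiny instance.
oracle_e_step <- function(Y, params, s, X, rho) {
  N <- nrow(Y); G <- ncol(Y); K <- ncol(rho)
  pi_k <- spanr::mixture_pi(params)
  gamma <- matrix(0, N, K)
  for (i in seq_len(N)) {
    w <- numeric(K)
    for (k in seq_len(K)) {
      lp <- log(pi_k[k])
      for (g in seq_len(G)) {
        mu <- oracle_mu(params, s, X, rho, i, g, k)
        lp <- lp + dnbinom(Y[i, g], size = oracle_phi(mu, params), mu = mu, log = TRUE)
      }
      w[k] <- lp
    }
    gamma[i, ] <- exp(w - max(w)) / sum(exp(w - max(w)))
  }
  gamma
}

# Random small mixture parameter set with the package's layout.
random_params <- function(G, K, P = 0, B = 3, ymax = 8, seed = 1) {
  withr::with_seed(seed, {
    centers <- seq(0, ymax, length.out = B)
    structure(list(
      delta_raw = matrix(rnorm(G * K, 0, 0.4), G, K),
      beta0 = rnorm(G, 0.5, 0.5),
      beta = matrix(rnorm(G * max(P, 0), 0, 0.3), G, P),
      a_raw = rnorm(B, 0.5, 0.5),
      b_raw = rnorm(B, -0.5, 0.5),
      centers = centers,
      pi_raw = rnorm(K, 0, 0.3),
      type_names = paste0("type", seq_len(K)),
      gene_names = paste0("gene", seq_len(G))), class = "mixture_params")
  })
}

random_instance <- function(N, G, K, P = 0, seed = 1) {
  withr::with_seed(seed, {
    Y <- matrix(rpois(N * G, 3), N, G,
                dimnames = list(paste0("s", 1:N), paste0("g", 1:G)))
    storage.mode(Y) <- "double"
    rho <- matrix(0, G, K)
    rho[cbind(seq_len(G), rep_len(seq_len(K), G))] <- 1
    extra <- matrix(rbinom(G * K, 1, 0.3), G, K)
    rho <- pmin(rho + extra, 1)
    dimnames(rho) <- list(colnames(Y), paste0("type", 1:K))
    list(Y = Y, rho = rho,
         s = runif(N, 0.5, 2),
         X = if (P > 0) matrix(rnorm(N * P), N, P) else matrix(0, N, 0))
  })
}

# Central finite differences of f at x.
fd_grad <- function(f, x, eps = 1e-4) {
  vapply(seq_along(x), function(i) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, numeric(1))
}

# Exhaustive per-spot conditionals of the label field: normalise the joint
# potential over all K^N configurations and condition on the rest.
brute_force_conditional <- function(graph, phi, z, i) {
  K <- phi$K
  n <- graph$n_spots
  w <- numeric(K)
  for (k in seq_len(K)) {
    zz <- z
    zz[i] <- k
    w[k] <- spanr::joint_log_potential(zz, graph, phi)
  }
  exp(w - max(w)) / sum(exp(w - max(w)))
}

small_sim <- function(seed = 1, n_spots = 100, n_genes = 600, K = 3, sigma = 0.6, ...) {
  spanr::simulate_dataset(spanr::sim_config(
    n_spots = n_spots, n_genes = n_genes, K = K, sigma = sigma, seed = seed, ...))
}
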