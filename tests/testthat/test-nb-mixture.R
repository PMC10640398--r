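test_that("size factors scale totals by their median and reject all-zero spots", {
  Y <- rbind(rep(25, 4), rep(50, 4), rep(75, 4))
  expect_equal(unname(compute_size_factors(Y)), c(0.5, 1.0, 1.5))
  expect_equal(unname(compute_size_factors(matrix(2, 3, 5))), rep(1, 3))
  expect_equal(unname(compute_size_factors(matrix(7, 1, 3))), 1)
  Yz <- rbind(c(1, 2), c(0, 0))
  rownames(Yz) <- c("good", "bad")
  err <- expect_error(compute_size_factors(Yz), class = "spanr_degenerate_spot")
  expect_match(conditionMessage(err), "bad")
})

test_that("nb_logpmf matches its closed form, normalises, and approaches Poisson", {
  expect_equal(nb_logpmf(0, 1, 1), log(1 / 2))
  # independent oracle: stats::dnbinom in the same mean/size convention
  withr::with_seed(5, {
    y <- rpois(50, 4); mu <- runif(50, 0.1, 10); phi <- runif(50, 0.2, 5)
    expect_equal(nb_logpmf(y, mu, phi), dnbinom(y, size = phi, mu = mu, log = TRUE),
                 tolerance = 1e-12)
  })
  expect_equal(sum(exp(nb_logpmf(0:10000, 5, 2))), 1, tolerance = 1e-8)
  expect_lt(abs(nb_logpmf(3, 2, 1e6) - dpois(3, 2, log = TRUE)), 1e-4)
  expect_error(nb_logpmf(1, -1, 1), class = "spanr_domain_error")
  expect_error(nb_logpmf(1.5, 1, 1), class = "spanr_domain_error")
})

test_that("log-mean model composes size factor, marker fold change and covariates", {
  params <- random_params(1, 1, P = 0, B = 1)
  params$delta_raw <- matrix(log(log(5)), 1, 1) # delta = ln 5
  params$beta0 <- log(3)
  rho1 <- matrix(1, 1, 1)
  lmu <- compute_log_mean(params, s = 2, X = NULL, rho = rho1)
  expect_equal(exp(lmu[1, 1, 1]), 30) # 2 * 5 * 3

  # all terms zero -> mu = 1
  p0 <- params; p0$beta0 <- 0
  expect_equal(exp(compute_log_mean(p0, 1, NULL, matrix(0, 1, 1))[1, 1, 1]), 1)

  # covariate multiplies the mean by exp(beta * x)
  p1 <- params
  p1$beta <- matrix(1, 1, 1)
  lmu1 <- compute_log_mean(p1, s = 2, X = matrix(0.5, 1, 1), rho = rho1)
  expect_equal(exp(lmu1[1, 1, 1]), 30 * exp(0.5))

  # marker monotonicity: flipping rho 0 -> 1 multiplies mu by exp(delta)
  expect_equal(exp(lmu[1, 1, 1]) / exp(compute_log_mean(params, 2, NULL,
                                                        matrix(0, 1, 1))[1, 1, 1]),
               exp(exp(params$delta_raw[1, 1])))
  expect_error(compute_log_mean(params, s = -1, X = NULL, rho = rho1),
               class = "spanr_invalid_size_factor")
})

test_that("RBF dispersion evaluates Gaussian bumps and stays positive", {
  p <- random_params(1, 1, B = 1)
  p$a_raw <- softplus_inv_t(2); p$b_raw <- -1e9; p$centers <- 0 # b ~ 0
  expect_equal(compute_dispersion(array(c(1, 5, 9), 3), p), rep(2, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
  p2 <- random_params(1, 1, B = 1)
  p2$a_raw <- softplus_inv_t(1); p2$b_raw <- softplus_inv_t(1); p2$centers <- 4
  expect_equal(compute_dispersion(array(4, 1), p2), 1, tolerance = 1e-9, ignore_attr = TRUE)
  p3 <- random_params(1, 1, B = 2)
  p3$a_raw <- rep(softplus_inv_t(1), 2); p3$b_raw <- rep(softplus_inv_t(1), 2)
  p3$centers <- c(0, 2)
  expect_equal(compute_dispersion(array(1, 1), p3), 2 * exp(-1), tolerance = 1e-9,
               ignore_attr = TRUE)
  # far from every centre the floor keeps phi positive
  expect_gt(compute_dispersion(array(1e5, 1), p3), 0)
})

test_that("e_step equals brute-force Bayes rule on small instances", {
  for (dims in list(c(2, 1, 2), c(3, 2, 2), c(4, 4, 4), c(2, 3, 4))) {
    inst <- random_instance(dims[1], dims[2], dims[3], seed = sum(dims))
    params <- random_params(dims[2], dims[3], B = 3, seed = sum(dims) + 1)
    gam <- e_step(inst$Y, params, inst$s, inst$X, inst$rho)
    expect_equal(unname(gam), oracle_e_step(inst$Y, params, inst$s, inst$X, inst$rho),
                 tolerance = 1e-12)
    expect_equal(rowSums(gam), rep(1, dims[1]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("e_step degenerates correctly for K = 1 and symmetric components", {
  inst <- random_instance(3, 2, 1, seed = 2)
  params <- random_params(2, 1)
  expect_equal(unname(e_step(inst$Y, params, inst$s, inst$X, inst$rho)),
               matrix(1, 3, 1))
  # two identical components with equal weights
  inst2 <- random_instance(3, 2, 2, seed = 3)
  inst2$rho <- matrix(1, 2, 2) # same markers for both types
  p2 <- random_params(2, 2)
  p2$delta_raw <- matrix(p2$delta_raw[, 1], 2, 2)
  p2$pi_raw <- c(0, 0)
  expect_equal(unname(e_step(inst2$Y, p2, inst2$s, inst2$X, inst2$rho)),
               matrix(0.5, 3, 2))
})

test_that("q_objective equals a term-by-term oracle and is exchangeable over spots", {
  inst <- random_instance(2, 1, 2, seed = 9)
  params <- random_params(1, 2, seed = 10)
  gam <- e_step(inst$Y, params, inst$s, inst$X, inst$rho)
  hyper <- mixture_hyperparams(B = 3)
  q <- q_objective(inst$Y, gam, params, inst$s, inst$X, inst$rho, hyper)
  # oracle: weighted log joint + priors, all by hand
  pi_k <- mixture_pi(params)
  qo <- 0
  for (i in 1:2) for (k in 1:2) {
    lp <- log(pi_k[k])
    for (g in 1) {
      mu <- oracle_mu(params, inst$s, inst$X, inst$rho, i, g, k)
      lp <- lp + dnbinom(inst$Y[i, g], size = oracle_phi(mu, params), mu = mu, log = TRUE)
    }
    qo <- qo + gam[i, k] * lp
  }
  d <- params$delta_raw[inst$rho == 1]
  qo <- qo + sum(-d - 0.5 * log(2 * pi * hyper$sigma2) - d^2 / (2 * hyper$sigma2))
  qo <- qo + sum((hyper$alpha - 1) * log(pi_k))
  expect_equal(q, qo, tolerance = 1e-12)

  # permuting spots leaves Q unchanged; doubling counts changes it
  perm <- c(2, 1)
  q_perm <- q_objective(inst$Y[perm, , drop = FALSE], gam[perm, , drop = FALSE],
                        params, inst$s[perm], inst$X, inst$rho, hyper)
  expect_equal(q, q_perm, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    q, q_objective(inst$Y * 2, gam, params, inst$s, inst$X, inst$rho, hyper))))

  # hard single-component labelling with priors off reduces to the NB loglik
  inst1 <- random_instance(3, 2, 1, seed = 4)
  p1 <- random_params(2, 1, seed = 5)
  q1 <- q_objective(inst1$Y, matrix(1, 3, 1), p1, inst1$s, inst1$X, inst1$rho,
                    include_priors = FALSE, include_pi = FALSE)
  ll <- sum(sapply(1:3, function(i) sum(sapply(1:2, function(g) {
    mu <- oracle_mu(p1, inst1$s, inst1$X, inst1$rho, i, g, 1)
    dnbinom(inst1$Y[i, g], size = oracle_phi(mu, p1), mu = mu, log = TRUE)
  }))))
  expect_equal(q1, ll, tolerance = 1e-10)
})

test_that("m_step with zero steps is the identity and otherwise never lowers Q", {
  inst <- random_instance(6, 3, 2, seed = 11)
  params <- random_params(3, 2, seed = 12)
  gam <- e_step(inst$Y, params, inst$s, inst$X, inst$rho)
  expect_identical(m_step(inst$Y, gam, params, inst$s, inst$X, inst$rho, n_steps = 0),
                   params)
  hyper <- mixture_hyperparams(B = 3)
  q0 <- q_objective(inst$Y, gam, params, inst$s, inst$X, inst$rho, hyper)
  p2 <- m_step(inst$Y, gam, params, inst$s, inst$X, inst$rho, hyper, n_steps = 25)
  q1 <- q_objective(inst$Y, gam, p2, inst$s, inst$X, inst$rho, hyper)
  expect_gte(q1, q0 - 1e-6)
})

test_that("single-gene single-type M-step approaches the mean-matching stationary point", {
  # gradient of the NB log-likelihood in mu vanishes at mu = weighted mean of y/s
  withr::with_seed(21, {
    N <- 60
    s <- runif(N, 0.5, 2)
    mu_true <- 4
    Y <- matrix(rnbinom(N, size = 5, mu = s * mu_true), N, 1)
    storage.mode(Y) <- "double"
  })
  rho <- matrix(1, 1, 1)
  gam <- matrix(1, N, 1)
  params <- random_params(1, 1, B = 2, ymax = max(Y))
  params$a_raw <- rep(softplus_inv_t(3), 2)
  params$b_raw <- rep(-20, 2) # flat dispersion, phi ~ 6
  target <- mean(Y / s)
  for (rep in 1:40) {
    params <- m_step(Y, gam, params, s, NULL, rho, include_priors = FALSE,
                     update_pi = FALSE, n_steps = 50, lr = 0.05)
  }
  mu_hat <- exp(exp(params$delta_raw[1, 1]) + params$beta0[1])
  expect_equal(mu_hat, target, tolerance = 1e-2)
})

test_that("EM fit is deterministic, monotone within tolerance, and recovers strong labels", {
  sim <- small_sim(seed = 42)
  mv <- spanr::marker_view(sim)
  fit1 <- fit_mixture(mv$Y, mv$rho, seed = 7)
  fit2 <- fit_mixture(mv$Y, mv$rho, seed = 7)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$gamma, fit2$gamma)

  expect_true(all(abs(rowSums(fit1$gamma) - 1) < 1e-8))
  expect_true(all(diff(fit1$history) > -1e-6 * abs(fit1$history[-length(fit1$history)])))

  acc <- score_assignment(sim$z_true, max.col(fit1$gamma))$accuracy
  expect_gte(acc, 0.9)
})

test_that("K = 1 mixture fit is trivial", {
  sim <- small_sim(seed = 3, n_spots = 30, n_genes = 300, K = 2)
  mv <- spanr::marker_view(sim)
  rho1 <- mv$rho[mv$rho[, 1] == 1, 1, drop = FALSE]
  fit <- fit_mixture(mv$Y[, rownames(rho1)], rho1, seed = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$gamma), matrix(1, 30, 1))
})
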