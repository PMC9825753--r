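test_that("posteriors match the defining ratio on a toy instance", {
  set.seed(3)
  x <- random_counts(G = 2, I = 2, J = 3, p_zero = 0.3)
  s <- upper_quartile_factors(x)
  params <- random_params(G = 2, I = 2, K = 2, s = s)
  Z <- e_step(x, params)
  expect_equal(unclass(Z), naive_e_step(x, params), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(rowSums(Z), rep(1, 2))
})

test_that("degenerate mixtures give trivial posteriors", {
  set.seed(4)
  x <- random_counts(G = 5, I = 2, J = 3)
  s <- upper_quartile_factors(x)
  p1 <- random_params(G = 5, I = 2, K = 1, s = s)
  p1$p <- 1
  expect_equal(as.vector(e_step(x, p1)), rep(1, 5))
  # two clusters with identical parameters and equal mixing: all 1/2
  p2 <- random_params(G = 5, I = 2, K = 2, s = s)
  p2$mu[2, ] <- p2$mu[1, ]; p2$gamma0[2, ] <- p2$gamma0[1, ]
  p2$gamma1[2, ] <- p2$gamma1[1, ]; p2$alpha[, 2] <- p2$alpha[, 1]
  Z <- e_step(x, p2)
  expect_equal(as.vector(Z), rep(0.5, 10))
})

test_that("mixing proportions update to posterior column means", {
  set.seed(5)
  x <- random_counts(G = 6, I = 2, J = 3)
  s <- upper_quartile_factors(x)
  params <- random_params(G = 6, I = 2, K = 3, s = s)
  Z <- matrix(0, 6, 3); Z[, 1] <- 1
  expect_equal(m_step(x, Z, params)$p, c(1, 0, 0))
  Zu <- matrix(1 / 3, 6, 3)
  expect_equal(m_step(x, Zu, params)$p, rep(1 / 3, 3))
})

test_that("the batched M step equals chaining the one-step updates", {
  set.seed(6)
  for (trial in 1:10) {
    x <- random_counts(G = 8, I = 3, J = 2, p_zero = 0.4)
    s <- upper_quartile_factors(x)
    params <- random_params(G = 8, I = 3, K = 3, s = s)
    Z <- e_step(x, params)
    a <- m_step(x, Z, params)
    b <- phclust:::.m_step_r(x, Z, params)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    expect_equal(a$mu, b$mu, tolerance = 1e-9)
    expect_equal(a$gamma0, b$gamma0, tolerance = 1e-9)
    expect_equal(a$gamma1, b$gamma1, tolerance = 1e-9)
    expect_equal(a$alpha, b$alpha, tolerance = 1e-9)
  }
})

test_that("each M step raises the total mixture log-likelihood", {
  set.seed(8)
  for (trial in 1:25) {
    x <- random_counts(G = 10, I = 2, J = 3, p_zero = 0.4)
    s <- upper_quartile_factors(x)
    params <- random_params(G = 10, I = 2, K = 2, s = s)
    Z <- e_step(x, params)
    after <- m_step(x, Z, params)
    expect_gte(total_loglik(x, after), total_loglik(x, params) - 1e-9)
  }
})

test_that("run_em converges with a monotone trace and argmax assignments", {
  sim <- simulate_dataset(simulation_config(G = 150, K = 3, eta_mu = 2,
                                            seed = 31))
  fit <- multi_start(sim$counts, 3, n_starts = 2, seed = 1)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_equal(fit$assignments, max.col(fit$posterior, ties.method = "first"))
  expect_equal(rowSums(fit$posterior), rep(1, 150), tolerance = 1e-10)
  expect_equal(fit$loglik, total_loglik(sim$counts, fit$params),
               tolerance = 1e-8)
})

test_that("a single-component fit is exact in the E step and still converges", {
  sim <- simulate_dataset(simulation_config(G = 80, K = 2, seed = 32))
  cm <- sim$counts
  s <- upper_quartile_factors(cm)
  init <- params_from_seeds(cm, 5, s = s)
  fit <- run_em(cm, 1, init)
  expect_true(fit$converged)
  expect_true(all(fit$posterior == 1))
  expect_true(all(fit$assignments == 1))
})

test_that("permuting the initial cluster order permutes the fit identically", {
  sim <- simulate_dataset(simulation_config(G = 100, K = 3, eta_mu = 2,
                                            seed = 33))
  cm <- sim$counts
  s <- upper_quartile_factors(cm)
  D <- tau_distance_matrix(cm)
  seeds <- select_seeds(D, 3, counts = cm)
  init <- params_from_seeds(cm, seeds, s = s)
  fit <- run_em(cm, 3, init)
  perm <- c(3, 1, 2)
  init_p <- hurdle_params(p = init$p[perm], mu = init$mu[perm, ],
                          gamma0 = init$gamma0[perm, ],
                          gamma1 = init$gamma1[perm, ],
                          alpha = init$alpha[, perm], s = s)
  fit_p <- run_em(cm, 3, init_p)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-8)
  # cluster j of the permuted fit is cluster perm[j] of the original
  expect_equal(fit_p$params$mu, fit$params$mu[perm, ], tolerance = 1e-6)
  expect_equal(perm[fit_p$assignments], fit$assignments)
})

test_that("well-separated clusters are recovered almost perfectly", {
  # strong separation, no zero inflation, Poisson counts
  aris <- vapply(1:20, function(sd) {
    sim <- simulate_dataset(simulation_config(G = 300, K = 4, eta_mu = 3,
                                              beta = 0, phi = 1, seed = sd))
    fit <- multi_start(sim$counts, 4, n_starts = 5, seed = sd)
    adjusted_rand_index(fit$assignments, sim$labels)
  }, numeric(1))
  expect_gte(median(aris), 0.95)
})

test_that("the reduced variant shares one abundance level per cluster", {
  sim <- simulate_dataset(simulation_config(G = 80, K = 2, eta_mu = 2,
                                            seed = 91))
  fit <- multi_start(sim$counts, 2, n_starts = 2, seed = 1,
                     variant = "reduced")
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # every alpha column is constant: one level per cluster
  expect_equal(unname(apply(fit$params$alpha, 2, function(a)
    diff(range(a)))), c(0, 0))
  # the full variant has more freedom, so it fits at least as well
  full <- multi_start(sim$counts, 2, n_starts = 2, seed = 1)
  expect_gte(full$loglik, fit$loglik)
})
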