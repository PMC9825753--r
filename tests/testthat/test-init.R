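test_that("tau distances match exhaustive pair counting and handle ties", {
  m <- rbind(c(1, 2, 3, 4),
             c(1, 3, 2, 4),
             c(4, 3, 2, 1),
             c(2, 2, 2, 2))
  x <- count_matrix(m, rep("a", 4))
  D <- tau_distance_matrix(x)
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_equal(D, t(D))
  # strictly reversed rankings, no ties: distance 2
  expect_equal(D[1, 3], 2)
  # one discordant pair out of six
  expect_equal(D[1, 2], 1 - naive_tau_b(m[1, ], m[2, ]))
  expect_equal(D[1, 2], 1 - 4 / 6)
  # constant feature: tau undefined, distance fixed at 1
  expect_equal(D[4, 1:3], rep(1, 3), ignore_attr = TRUE)
})

test_that("tau_b agrees with stats::cor on tie-heavy random vectors", {
  set.seed(55)
  for (trial in 1:200) {
    a <- rpois(8, 2) * rbinom(8, 1, 0.7)
    b <- rpois(8, 2) * rbinom(8, 1, 0.7)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    x <- count_matrix(rbind(a, b), rep("t", 8))
    D <- tau_distance_matrix(x)
    expect_equal(D[1, 2], 1 - cor(a, b, method = "kendall"),
                 tolerance = 1e-12)
  }
})

test_that("seed selection is greedy maximin with a deterministic anchor", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 0.1
  D[1, 3] <- D[3, 1] <- 1.9
  D[2, 3] <- D[3, 2] <- 1.9
  expect_equal(select_seeds(D, 2, first_seed = 1), c(1L, 3L))
  expect_equal(select_seeds(D, 3, first_seed = 1), c(1L, 3L, 2L))
  expect_equal(select_seeds(D, 1, first_seed = 2), 2L)
  expect_error(select_seeds(D, 4, first_seed = 1), "exceed")

  set.seed(66)
  x <- random_counts(G = 10, I = 2, J = 3)
  Dx <- tau_distance_matrix(x)
  s1 <- select_seeds(Dx, 4, counts = x)
  s2 <- select_seeds(Dx, 4, counts = x)
  expect_identical(s1, s2)
  expect_equal(s1[1], unname(which.max(rowSums(x$counts))))
})

test_that("seed parameters start at uniform mixing with per-seed MLEs", {
  set.seed(67)
  x <- random_counts(G = 12, I = 2, J = 4, p_zero = 0.3)
  s <- upper_quartile_factors(x)
  init <- params_from_seeds(x, c(2, 7, 11), s = s)
  expect_equal(init$p, rep(1 / 3, 3))
  expect_equal(dim(init$alpha), c(12, 3))
  expect_true(all(abs(rowSums(init$mu)) < 1e-8))
  expect_error(params_from_seeds(x, c(2, 2), s = s), "distinct")
})

test_that("a seed with constant positive counts yields zero treatment effects", {
  m <- rbind(rep(4, 6), matrix(rpois(18, 2) + 1, 3, 6))
  x <- count_matrix(m, rep(c("a", "b"), each = 3))
  init <- params_from_seeds(x, 1, s = rep(0, 6))
  expect_equal(init$mu[1, ], c(0, 0), tolerance = 1e-6)
})

test_that("a seed silent in one treatment keeps that effect at zero", {
  m <- rbind(c(3, 4, 2, 0, 0, 0), matrix(rpois(18, 2) + 1, 3, 6))
  x <- count_matrix(m, rep(c("a", "b"), each = 3))
  init <- params_from_seeds(x, 1, s = rep(0, 6))
  # sum-to-zero re-centering spreads the observed effect; the silent
  # treatment contributes no truncated-Poisson information of its own
  expect_true(all(is.finite(init$mu)))
  expect_equal(sum(init$mu[1, ]), 0, tolerance = 1e-10)
})

test_that("the single-seed fit maximizes the one-feature hurdle likelihood", {
  set.seed(68)
  v <- c(5, 0, 3, 7, 0, 4)
  x <- count_matrix(rbind(v, matrix(1, 1, 6)), rep("a", 6))
  s <- seq(-0.25, 0.25, length.out = 6)
  init <- params_from_seeds(x, 1, s = s)
  w <- c(1, 0)
  ll_ours <- cluster_loglik(x, w, get_cluster(init, 1), init$alpha[, 1], s)
  obj <- function(th) {
    cand <- cluster_params(mu = 0, gamma0 = th[2], gamma1 = max(th[3], 0),
                           p = 1)
    -cluster_loglik(x, w, cand, c(th[1], 0), s)
  }
  opt <- optim(c(1, 0, 0.1), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_lte(abs(ll_ours - (-opt$value)), 1e-5)
})

test_that("multi-start returns the best start and is reproducible", {
  sim <- simulate_dataset(simulation_config(G = 100, K = 3, eta_mu = 1.5,
                                            seed = 71))
  fit <- multi_start(sim$counts, 3, n_starts = 4, seed = 9)
  expect_equal(fit$loglik, max(fit$start_logliks))
  expect_length(fit$start_logliks, 4)
  refit <- multi_start(sim$counts, 3, n_starts = 4, seed = 9)
  expect_identical(fit$assignments, refit$assignments)
  expect_equal(fit$loglik, refit$loglik)
  # one start equals the deterministic seeding run
  one <- multi_start(sim$counts, 3, n_starts = 1, seed = 1)
  cm <- sim$counts
  s <- upper_quartile_factors(cm)
  det <- run_em(cm, 3, params_from_seeds(
    cm, select_seeds(tau_distance_matrix(cm), 3, counts = cm), s = s))
  expect_equal(one$loglik, det$loglik)
})
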