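test_that("hurdle log pmf matches its defining two-branch formula", {
  expect_equal(hurdle_log_pmf(0, 5, 0.3), log(0.7))
  expect_equal(hurdle_log_pmf(2, 1, 0.5),
               log(0.5 * exp(-1) / (2 * (1 - exp(-1)))))
  # normalization over the support for a grid of (lam, q)
  for (lam in c(0.2, 2, 9)) {
    for (q in c(0, 0.3, 1)) {
      expect_equal(sum(exp(hurdle_log_pmf(0:200, lam, q))), 1,
                   tolerance = 1e-12)
    }
  }
  expect_error(hurdle_log_pmf(-1, 2, 0.5), "non-negative")
  expect_error(hurdle_log_pmf(1.5, 2, 0.5), "non-negative integers")
  expect_identical(hurdle_log_pmf(3, 2, 0), -Inf)
})

test_that("with q equal to the Poisson positive mass the hurdle collapses to Poisson", {
  for (lam in c(0.5, 1, 4, 12)) {
    q <- 1 - exp(-lam)
    expect_equal(hurdle_log_pmf(0:30, lam, q), dpois(0:30, lam, log = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("cluster_loglik agrees with a term-by-term naive evaluation", {
  set.seed(42)
  x <- random_counts(G = 3, I = 2, J = 3)
  s <- upper_quartile_factors(x)
  cl <- cluster_params(mu = c(0.3, -0.3), gamma0 = c(0.2, -0.1),
                       gamma1 = c(0.5, 0), p = 1)
  alpha_col <- c(0.5, 1.2, 0.8)
  w <- c(0.2, 1, 0.7)
  expect_equal(cluster_loglik(x, w, cl, alpha_col, s),
               unname(naive_cluster_loglik(x, w, cl, alpha_col, s)),
               tolerance = 1e-10)
  # zero weights mean zero contribution
  expect_equal(cluster_loglik(x, rep(0, 3), cl, alpha_col, s), 0)
  # single unit weight reduces to a sum of pmf terms for that feature
  w1 <- c(0, 1, 0)
  direct <- sum(vapply(seq_len(n_samples(x)), function(n) {
    i <- as.integer(x$treatment)[n]
    naive_hurdle_log_pmf(x$counts[2, n],
                         exp(s[n] + alpha_col[2] + cl$mu[i]),
                         plogis(cl$gamma0[i] + cl$gamma1[i] * s[n]))
  }, numeric(1)))
  expect_equal(cluster_loglik(x, w1, cl, alpha_col, s), direct,
               tolerance = 1e-10)
})

test_that("gamma update hits boundary and Bernoulli closed forms", {
  # all observations positive in every treatment: gamma0 runs to the +12 clamp
  m <- matrix(rpois(24, 4) + 1, 4, 6)
  x <- count_matrix(m, rep(c("a", "b"), each = 3))
  s <- rep(0, 6)
  cl <- cluster_params(mu = c(0, 0), gamma0 = c(0, 0), gamma1 = c(0, 0), p = 1)
  for (it in 1:60) cl <- update_gamma(x, rep(1, 4), cl, s)
  expect_equal(cl$gamma0, c(12, 12))

  # with s = 0 the converged intercept is the logit of the weighted
  # positive fraction
  set.seed(9)
  m <- matrix(rpois(40, 1.2) * rbinom(40, 1, 0.6), 8, 5)
  m[1, ] <- c(1, 2, 0, 0, 3)  # keep a mixed pattern in row 1
  x <- count_matrix(m, rep("a", 5))
  w <- runif(8)
  cl <- cluster_params(mu = 0, gamma0 = 0, gamma1 = 0, p = 1)
  for (it in 1:200) cl <- update_gamma(x, w, cl, rep(0, 5))
  frac <- sum(w * rowMeans(m > 0)) / sum(w)
  expect_equal(cl$gamma0, qlogis(frac), tolerance = 1e-6)
  expect_equal(cl$gamma1, 0)
})

test_that("iterated gamma one-steps reach the numerical maximizer", {
  set.seed(7)
  x <- random_counts(G = 5, I = 2, J = 4, p_zero = 0.4)
  s <- upper_quartile_factors(x)
  w <- runif(5, 0.2, 1)
  cl <- cluster_params(mu = c(0, 0), gamma0 = c(0, 0), gamma1 = c(0.1, 0.1),
                       p = 1)
  alpha_col <- rep(1, 5)
  for (it in 1:400) cl <- update_gamma(x, w, cl, s)
  ll_ours <- cluster_loglik(x, w, cl, alpha_col, s)
  # generic constrained maximizer of the gamma part (alpha/mu fixed)
  obj <- function(th) {
    cand <- cluster_params(mu = cl$mu, gamma0 = th[1:2],
                           gamma1 = pmax(th[3:4], 0), p = 1)
    -cluster_loglik(x, w, cand, alpha_col, s)
  }
  opt <- optim(c(0, 0, 0.1, 0.1), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_lte(abs(ll_ours - (-opt$value)), 1e-6)
})

test_that("iterated alpha/mu one-steps reach the constrained maximizer", {
  set.seed(13)
  # no zeros so the truncated-Poisson part is fully identified
  m <- matrix(rpois(24, 6) + 1, 4, 6)
  x <- count_matrix(m, rep(c("a", "b"), each = 3))
  s <- upper_quartile_factors(x)
  w <- runif(4, 0.3, 1)
  cl <- cluster_params(mu = c(0, 0), gamma0 = c(2, 2), gamma1 = c(0, 0), p = 1)
  alpha_col <- rep(1, 4)
  for (it in 1:500) {
    up <- update_alpha_mu(x, w, cl, alpha_col, s)
    cl <- up$cluster; alpha_col <- up$alpha_col
  }
  ll_ours <- cluster_loglik(x, w, cl, alpha_col, s)
  # generic maximizer over (alpha_1..4, mu_free) with sum-zero mu
  obj <- function(th) {
    mu <- c(th[5], -th[5])
    cand <- cluster_params(mu = mu, gamma0 = cl$gamma0, gamma1 = cl$gamma1,
                           p = 1)
    -cluster_loglik(x, w, cand, th[1:4], s)
  }
  opt <- optim(c(alpha_col, 0), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lte(abs(ll_ours - (-opt$value)), 1e-5)
})

test_that("symmetric data drive the treatment effects to zero", {
  # identical positive counts in both treatments, s = 0
  m <- matrix(rep(c(3, 5, 2, 4), 6), 4, 6)
  x <- count_matrix(m, rep(c("a", "b"), each = 3))
  cl <- cluster_params(mu = c(0.4, -0.4), gamma0 = c(1, 1), gamma1 = c(0, 0),
                       p = 1)
  alpha_col <- rep(1, 4)
  for (it in 1:300) {
    up <- update_alpha_mu(x, rep(1, 4), cl, alpha_col, rep(0, 6))
    cl <- up$cluster; alpha_col <- up$alpha_col
  }
  expect_equal(cl$mu, c(0, 0), tolerance = 1e-6)
})

test_that("one-step updates never decrease the cluster log-likelihood", {
  set.seed(100)
  for (trial in 1:40) {
    x <- random_counts(G = 6, I = 2, J = 3, p_zero = 0.4)
    s <- upper_quartile_factors(x)
    w <- runif(6)
    mu <- rnorm(2, 0, 0.5); mu <- mu - mean(mu)
    cl <- cluster_params(mu = mu, gamma0 = rnorm(2), gamma1 = runif(2, 0, 1),
                         p = 1)
    alpha_col <- rnorm(6, 1, 0.6)
    ll0 <- cluster_loglik(x, w, cl, alpha_col, s)
    cl1 <- update_gamma(x, w, cl, s)
    ll1 <- cluster_loglik(x, w, cl1, alpha_col, s)
    expect_gte(ll1, ll0 - 1e-10)
    up <- update_alpha_mu(x, w, cl1, alpha_col, s)
    ll2 <- cluster_loglik(x, w, up$cluster, up$alpha_col, s)
    expect_gte(ll2, ll1 - 1e-10)
  }
})

test_that("alpha/mu update respects the location identifiability", {
  set.seed(21)
  x <- random_counts(G = 5, I = 2, J = 3, p_zero = 0.3)
  s <- upper_quartile_factors(x)
  w <- runif(5)
  mu <- c(0.3, -0.3)
  cl <- cluster_params(mu = mu, gamma0 = c(0.5, 0.5), gamma1 = c(0.2, 0.2),
                       p = 1)
  alpha_col <- rnorm(5, 1, 0.3)
  ref <- update_alpha_mu(x, w, cl, alpha_col, s)
  # shift c into mu and out of alpha: the fitted model is unchanged, and so
  # must be the (re-centered) output
  cc <- 0.37
  cl_sh <- phclust:::.cluster_params_fast(mu + cc, cl$gamma0, cl$gamma1, 1)
  sh <- update_alpha_mu(x, w, cl_sh, alpha_col - cc, s)
  expect_equal(ref$cluster$mu, sh$cluster$mu, tolerance = 1e-9)
  expect_equal(ref$alpha_col, sh$alpha_col, tolerance = 1e-9)
})

test_that("all-zero features keep their alpha and carry only the zero branch", {
  # features 1 and 2 have no positive counts: their truncated-Poisson part
  # is undefined, so their alpha moves only by the global re-centering
  # shift that every alpha receives
  m <- matrix(c(0, 0, 0, 0, 0, 0,
                0, 0, 0, 0, 0, 0,
                2, 1, 3, 2, 4, 1), 3, 6, byrow = TRUE)
  x <- count_matrix(m, rep(c("a", "b"), each = 3))
  cl <- cluster_params(mu = c(0, 0), gamma0 = c(0, 0), gamma1 = c(0, 0), p = 1)
  up <- update_alpha_mu(x, c(1, 1, 1), cl, c(5, 1, 1), rep(0, 6))
  shift1 <- up$alpha_col[1] - 5
  shift2 <- up$alpha_col[2] - 1
  expect_equal(shift1, shift2, tolerance = 1e-12)
  expect_equal(sum(up$cluster$mu), 0, tolerance = 1e-12)
})

test_that("parameter containers validate their invariants", {
  expect_error(cluster_params(mu = c(1, 0), gamma0 = c(0, 0),
                              gamma1 = c(0, 0)), "sum to zero")
  expect_error(cluster_params(mu = c(0.5, -0.5), gamma0 = c(0, 0),
                              gamma1 = c(-1, 0)), "non-negative")
  expect_error(hurdle_params(p = c(0.6, 0.6), mu = matrix(0, 2, 2),
                             gamma0 = matrix(0, 2, 2),
                             gamma1 = matrix(0, 2, 2),
                             alpha = matrix(0, 3, 2), s = rep(0, 4)),
               "sum to 1")
  p <- hurdle_params(p = c(0.5, 0.5), mu = matrix(0, 2, 3),
                     gamma0 = matrix(0, 2, 3), gamma1 = matrix(0, 2, 3),
                     alpha = matrix(1, 4, 2), s = rep(0, 6))
  cl <- get_cluster(p, 2)
  expect_s3_class(cl, "cluster_params")
  expect_equal(cl$p, 0.5)
})
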