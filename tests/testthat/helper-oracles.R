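# Independent oracles: deliberately naive re-implementations used to check
# the package's vectorized / compiled paths, plus small fixture builders.

# direct transcription of the two-branch hurdle pmf, scalar only
naive_hurdle_log_pmf <- function(n, lam, q) {
  if (n == 0) return(log(1 - q))
  log(q) - log(1 - exp(-lam)) + n * log(lam) - lam - lgamma(n + 1)
}

# term-by-term weighted cluster log-likelihood from the model definition
naive_cluster_loglik <- function(counts, weights, cluster, alpha_col, s) {
  ti <- as.integer(counts$treatment)
  tot <- 0
  for (g in seq_len(n_features(counts))) {
    for (n in seq_len(n_samples(counts))) {
      i <- ti[n]
      lam <- exp(s[n] + alpha_col[g] + cluster$mu[i])
      q <- stats::plogis(cluster$gamma0[i] + cluster$gamma1[i] * s[n])
      tot <- tot + weights[g] *
        naive_hurdle_log_pmf(counts$counts[g, n], lam, q)
    }
  }
  tot
}

# posterior memberships straight from the defining ratio, no log space
naive_e_step <- function(counts, params) {
  G <- n_features(counts)
  K <- length(params$p)
  ti <- as.integer(counts$treatment)
  Z <- matrix(0, G, K)
  for (g in seq_len(G)) {
    for (k in seq_len(K)) {
      f <- 1
      for (n in seq_len(n_samples(counts))) {
        i <- ti[n]
        lam <- exp(params$s[n] + params$alpha[g, k] + params$mu[k, i])
        q <- stats::plogis(params$gamma0[k, i] + params$gamma1[k, i] *
                             params$s[n])
        f <- f * exp(naive_hurdle_log_pmf(counts$counts[g, n], lam, q))
      }
      Z[g, k] <- params$p[k] * f
    }
  }
  Z / rowSums(Z)
}

# tie-corrected Kendall tau_b by exhaustive pair counting
naive_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      dx <- x[u] - x[v]; dy <- y[u] - y[v]
      if (dx == 0) tx <- tx + 1
      if (dy == 0) ty <- ty + 1
      if (dx * dy > 0) conc <- conc + 1
      if (dx * dy < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  (conc - disc) / den
}

# adjusted Rand index by exhaustive pair agreement counting
naive_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      sa <- a[u] == a[v]; sb <- b[u] == b[v]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  np <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / np
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# small random count matrix with treatment structure and plenty of zeros
random_counts <- function(G = 4, I = 2, J = 3, lambda = 3, p_zero = 0.3,
                          min_pos = TRUE) {
  N <- I * J
  m <- matrix(rpois(G * N, lambda) * rbinom(G * N, 1, 1 - p_zero), G, N)
  if (min_pos) {
    # ensure every sample has a nonzero count so UQ factors exist
    for (n in seq_len(N)) if (all(m[, n] == 0)) m[sample(G, 1), n] <- 1
  }
  count_matrix(m, rep(paste0("t", seq_len(I)), each = J))
}

# random valid mixture parameters for a given dataset shape
random_params <- function(G, I, K, s) {
  mu <- matrix(rnorm(K * I, 0, 0.5), K, I)
  mu <- mu - rowMeans(mu)
  hurdle_params(p = rep(1 / K, K), mu = mu,
                gamma0 = matrix(rnorm(K * I, 0, 1), K, I),
                gamma1 = matrix(runif(K * I, 0, 0.5), K, I),
                alpha = matrix(rnorm(G * K, 1, 0.5), G, K),
                s = s)
}

# all permutations of 1..k (small k), for label matching
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

# RMSE between fitted and true treatment-effect matrices under the best
# row permutation
matched_mu_rmse <- function(mu_hat, mu_true) {
  best <- Inf
  for (p in all_perms(seq_len(nrow(mu_true))))
    best <- min(best, sqrt(mean((mu_hat - mu_true[p, , drop = FALSE])^2)))
  best
}
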