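#' Treatment-effect profiles of the simulated clusters
#'
#' The seven clusters' direction-of-change profiles across the three
#' treatment groups: the six permutations of (positive, none, negative)
#' effect plus an all-zero profile for non-differential features. Each row
#' sums to zero. Multiplied by the effect magnitude `eta_mu` these give the
#' treatment effects `mu_ki`.
#'
#' @return `7 x 3` numeric matrix
#' @export
delta_profiles <- function() {
  matrix(c(0, 1, -1,
           0, -1, 1,
           1, 0, -1,
           -1, 0, 1,
           1, -1, 0,
           -1, 1, 0,
           0, 0, 0), nrow = 7, byrow = TRUE,
         dimnames = list(paste0("k", 1:7), paste0("i", 1:3)))
}

#' Cluster-by-treatment target positive-count rates, scenario 1
#'
#' In the structured zero-inflation scenario, each cluster-treatment cell has
#' its own target mean probability of a positive count: the six permutations
#' of (high, medium, low) = (0.9, 0.6, 0.3) plus one uniform (0.5, 0.5, 0.5)
#' row for the non-differential cluster.
#'
#' @return `7 x 3` numeric matrix
#' @export
scenario1_qbar <- function() {
  matrix(c(0.9, 0.6, 0.3,
           0.9, 0.3, 0.6,
           0.3, 0.9, 0.6,
           0.6, 0.9, 0.3,
           0.3, 0.6, 0.9,
           0.6, 0.3, 0.9,
           0.5, 0.5, 0.5), nrow = 7, byrow = TRUE,
         dimnames = list(paste0("k", 1:7), paste0("i", 1:3)))
}

#' Simulation configuration
#'
#' All knobs of the zero-inflated negative-binomial generator. The defaults
#' are the study conditions used throughout the package's experiments:
#' `G = 1000` features in `K = 7` equally mixed clusters, `I = 3` treatments
#' with `J = 5` replicates, overdispersion `beta = 0.02`, effect magnitude
#' `eta_mu = 1`, uniform positive-rate target `phi = 0.4` (scenario 2) and
#' average sequencing depth `C = 10` reads per feature.
#'
#' @param G,I,J,K numbers of features, treatments, replicates per treatment
#'   and true clusters
#' @param mixing length-`K` mixing proportions (default uniform)
#' @param beta overdispersion coefficient in `[0, 0.5]`; the negative
#'   binomial variance is `(1 + beta * exp(alpha_g)) * mean`, so `beta = 0`
#'   is exactly Poisson
#' @param eta_mu magnitude of the treatment effects, `mu_ki = eta_mu *
#'   delta_ki`
#' @param scenario `1` (structured per-cluster positive rates,
#'   [scenario1_qbar]) or `2` (common rate `phi`)
#' @param phi scenario-2 target mean probability of a positive count, in
#'   `(0, 1]`; `phi = 1` means no zero inflation
#' @param qbar `K x I` matrix of scenario-1 targets; defaults to
#'   [scenario1_qbar] when `K = 7`, `I = 3`
#' @param C average sequencing depth: every sample column is resampled to
#'   exactly `C * G` total counts
#' @param seed optional integer seed
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(G = 1000, I = 3, J = 5, K = 7, mixing = NULL,
                              beta = 0.02, eta_mu = 1, scenario = 2,
                              phi = 0.4, qbar = NULL, C = 10, seed = NULL) {
  if (is.null(mixing)) mixing <- rep(1 / K, K)
  if (abs(sum(mixing) - 1) > 1e-8) stop("mixing must sum to 1")
  if (length(mixing) != K) stop("mixing must have length K")
  if (beta < 0) stop("beta must be non-negative")
  if (!scenario %in% c(1, 2)) stop("scenario must be 1 or 2")
  if (scenario == 2 && (phi <= 0 || phi > 1)) stop("phi must be in (0, 1]")
  if (scenario == 1) {
    if (is.null(qbar)) {
      if (K == 7 && I == 3) qbar <- scenario1_qbar()
      else stop("scenario 1 requires a K x I qbar matrix")
    }
    qbar <- as.matrix(qbar)
    if (nrow(qbar) != K || ncol(qbar) != I)
      stop("qbar must be K x I")
    if (any(qbar <= 0 | qbar > 1)) stop("qbar entries must be in (0, 1]")
  }
  structure(list(G = G, I = I, J = J, K = K, mixing = mixing, beta = beta,
                 eta_mu = eta_mu, scenario = scenario, phi = phi,
                 qbar = qbar, C = C, seed = seed),
            class = "simulation_config")
}

#' Solve the zero-part intercept for a target mean positive rate
#'
#' Finds `gamma0` such that the mean of
#' `plogis(gamma0 + gamma1 * s_j + gamma2 * alpha_g)` over all `(g, j)`
#' combinations equals `qbar_target`. The mean is strictly increasing in
#' `gamma0`, so a bisection on `[-50, 50]` converges to tolerance 1e-10.
#' With `gamma1 = gamma2 = 0` the closed form `qlogis(qbar_target)` is
#' returned by the same bisection.
#'
#' @param qbar_target target mean positive probability in `(0, 1)`; a target
#'   of exactly 1 returns the upper bound 50 with a warning
#' @param gamma1,gamma2 non-negative slopes on `s` and `alpha`
#' @param s_vec normalization factors of the samples in the cell
#' @param alpha_vec abundance levels of the features in the cell
#' @return scalar `gamma0`
#' @export
solve_gamma0 <- function(qbar_target, gamma1, gamma2, s_vec, alpha_vec) {
  stopifnot(qbar_target > 0, qbar_target <= 1, gamma1 >= 0, gamma2 >= 0)
  if (qbar_target == 1) {
    warning("target positive rate 1 is attained only in the limit; returning 50")
    return(50)
  }
  off <- as.vector(outer(gamma2 * alpha_vec, gamma1 * s_vec, "+"))
  f <- function(g0) mean(stats::plogis(g0 + off)) - qbar_target
  lo <- -50; hi <- 50
  if (f(lo) > 0) return(lo)
  if (f(hi) < 0) return(hi)
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a zero-inflated negative-binomial microbiome dataset
#'
#' Generates a feature table with known cluster structure: cluster labels are
#' multinomial with the configured mixing proportions; abundance levels
#' `alpha_g` and depth factors `s_ij` are Uniform(0.8, 1.2); treatment
#' effects are `mu_ki = eta_mu * delta_ki` ([delta_profiles]); each
#' observation is the product of a Bernoulli gate (probability
#' `plogis(gamma0_ki + gamma1_ki s_ij + gamma2_ki alpha_g)`, with `gamma1,
#' gamma2 ~ Uniform(0, 0.5)` and `gamma0` solved so the realized mean gate
#' probability in each cluster-treatment cell hits its target) and a negative
#' binomial draw with mean `exp(s_ij + alpha_g + mu_ki)` and variance
#' `(1 + beta exp(alpha_g)) * mean`. Finally each sample column is
#' multinomially resampled to exactly `C * G` total counts, mimicking
#' sequencing and inducing compositional dependence among features.
#'
#' Note the gate's `gamma2 * alpha_g` term is absent from the fitted model's
#' zero part, so the generator is deliberately mildly misspecified relative
#' to the estimator.
#'
#' @param config a [simulation_config]
#' @return list of class `sim_dataset` with `counts` (a [count_matrix]),
#'   `labels` (true cluster of each feature), `raw` and `gate` (the
#'   pre-resampling counts and Bernoulli gate indicators, kept for moment
#'   checks) and `truth` (the generating parameters: `alpha`, `s`, `mu`,
#'   `gamma0`, `gamma1`, `gamma2`, targets, per-feature overdispersion rate)
#' @examples
#' sim <- simulate_dataset(simulation_config(G = 100, seed = 1))
#' colSums(sim$counts$counts)  # all exactly C * G
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  G <- config$G; I <- config$I; J <- config$J; K <- config$K
  N <- I * J
  treat <- rep(seq_len(I), each = J)
  labels <- sample.int(K, G, replace = TRUE, prob = config$mixing)
  alpha <- stats::runif(G, 0.8, 1.2)
  s <- stats::runif(N, 0.8, 1.2)
  delta <- if (K == 7 && I == 3) delta_profiles() else
    .recycled_profiles(K, I)
  mu <- config$eta_mu * delta
  qtarget <- if (config$scenario == 1) config$qbar else
    matrix(config$phi, K, I)
  g1 <- matrix(stats::runif(K * I, 0, 0.5), K, I)
  g2 <- matrix(stats::runif(K * I, 0, 0.5), K, I)
  g0 <- matrix(0, K, I)
  for (k in seq_len(K)) {
    gk <- which(labels == k)
    avec <- if (length(gk) > 0) alpha[gk] else alpha
    for (i in seq_len(I)) {
      g0[k, i] <- if (qtarget[k, i] == 1) 50 else
        solve_gamma0(qtarget[k, i], g1[k, i], g2[k, i],
                     s[treat == i], avec)
    }
  }
  raw <- matrix(0L, G, N)
  gate_mat <- matrix(0L, G, N)
  for (i in seq_len(I)) {
    cols <- which(treat == i)
    for (n in cols) {
      q <- stats::plogis(g0[cbind(labels, i)] + g1[cbind(labels, i)] * s[n] +
                           g2[cbind(labels, i)] * alpha)
      gate <- stats::rbinom(G, 1, q)
      m <- exp(s[n] + alpha + mu[cbind(labels, i)])
      y <- if (config$beta == 0) {
        stats::rpois(G, m)
      } else {
        stats::rnbinom(G, mu = m, size = m / (config$beta * exp(alpha)))
      }
      raw[, n] <- gate * y
      gate_mat[, n] <- gate
    }
  }
  total <- config$C * G
  counts <- matrix(0L, G, N)
  for (n in seq_len(N)) {
    cs <- sum(raw[, n])
    prob <- if (cs > 0) raw[, n] / cs else rep(1 / G, G)
    counts[, n] <- as.integer(stats::rmultinom(1, total, prob))
  }
  rownames(counts) <- sprintf("f%04d", seq_len(G))
  colnames(counts) <- sprintf("t%d_r%d", treat, rep(seq_len(J), times = I))
  cm <- count_matrix(counts, factor(paste0("t", treat)))
  structure(list(counts = cm,
                 labels = labels,
                 raw = raw,
                 gate = gate_mat,
                 truth = list(alpha = alpha, s = s, mu = mu, gamma0 = g0,
                              gamma1 = g1, gamma2 = g2, qbar = qtarget,
                              beta_rate = config$beta * exp(alpha),
                              labels = labels)),
            class = "sim_dataset")
}

# direction profiles for non-default (K, I): signed spread across treatments,
# last cluster flat, every row centered to sum to zero
.recycled_profiles <- function(K, I) {
  base <- matrix(0, K, I)
  for (k in seq_len(K - 1)) {
    v <- sin(2 * pi * (seq_len(I) - 1) / I + 2 * pi * (k - 1) / max(1, K - 1))
    base[k, ] <- v - mean(v)
  }
  base
}
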