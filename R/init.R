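#' Kendall's tau-b distance matrix between features
#'
#' Pairwise `1 - tau_b` over the count vectors of each pair of features.
#' The tie-corrected tau_b is used because microbiome count vectors are
#' tie-heavy (many shared zeros). A feature with a constant count vector has
#' undefined tau; its distance to everything is set to the uninformative
#' value 1. Distances lie in `[0, 2]` with 0 on the diagonal.
#'
#' @param counts a [count_matrix] (G >= 2 features)
#' @return symmetric `G x G` numeric matrix
#' @export
tau_distance_matrix <- function(counts) {
  stopifnot(n_features(counts) >= 2)
  D <- cpp_tau_distance(counts$counts)
  dimnames(D) <- list(rownames(counts$counts), rownames(counts$counts))
  D
}

#' Greedy maximin selection of well-separated seed features
#'
#' Picks `K` features that are far apart under a distance matrix: the first
#' seed is the feature with the largest total count (a deterministic,
#' reproducible anchor; ties broken by lowest index) unless `first_seed` is
#' given, and each subsequent seed maximizes its minimum distance to the
#' seeds already chosen (ties again by lowest index).
#'
#' @param D `G x G` distance matrix (see [tau_distance_matrix])
#' @param K number of seeds, `1 <= K <= G`
#' @param counts the [count_matrix], used for the default first-seed rule
#' @param first_seed optional index of the first seed (used for randomized
#'   restarts)
#' @return integer vector of `K` distinct feature indices
#' @export
select_seeds <- function(D, K, counts = NULL, first_seed = NULL) {
  G <- nrow(D)
  if (K > G) stop("K cannot exceed the number of features")
  if (is.null(first_seed)) {
    if (is.null(counts)) stop("either counts or first_seed must be supplied")
    first_seed <- which.max(rowSums(counts$counts))
  }
  seeds <- as.integer(unname(first_seed))
  if (K == 1L) return(seeds)
  mind <- unname(D[, seeds[1]])
  for (j in 2:K) {
    mind[seeds] <- -Inf
    nxt <- which.max(mind)  # which.max breaks ties by lowest index
    seeds <- c(seeds, nxt)
    mind <- pmin(mind, unname(D[, nxt]))
  }
  seeds
}

#' Starting parameters from seed features
#'
#' Builds a full [hurdle_params] initialization from `K` seed features: each
#' seed is fitted on its own by iterating the one-step hurdle updates to
#' convergence (a single-feature maximum-likelihood fit), giving that
#' cluster's `mu` and `gamma`; mixing proportions start uniform at `1/K`;
#' and every feature's abundance level `alpha_g` is initialized from its own
#' log mean positive count (adjusted for the normalization factors), the same
#' value in every cluster column. A seed with no positive counts in some
#' treatment keeps `mu = 0` for that component.
#'
#' @param counts a [count_matrix]
#' @param seeds distinct feature indices (length `K`)
#' @param s normalization factors (defaults to [upper_quartile_factors])
#' @param variant `"full"` or `"reduced"`
#' @return a [hurdle_params]
#' @export
params_from_seeds <- function(counts, seeds, s = NULL,
                              variant = c("full", "reduced")) {
  variant <- match.arg(variant)
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  if (is.null(s)) s <- upper_quartile_factors(counts)
  K <- length(seeds)
  G <- n_features(counts)
  I <- nlevels(counts$treatment)
  mu <- matrix(0, K, I); g0 <- matrix(0, K, I); g1 <- matrix(0, K, I)
  alpha <- matrix(.alpha_start(counts, s), G, K)
  for (k in seq_len(K)) {
    fit <- .single_feature_fit(counts, seeds[k], s)
    # the hurdle likelihood separates, so the clamped logistic part can be
    # polished on its own with the guarded one-step update
    w <- numeric(G); w[seeds[k]] <- 1
    cl <- .cluster_params_fast(fit$mu, fit$gamma0, fit$gamma1, 1)
    for (it in 1:30) cl <- update_gamma(counts, w, cl, s)
    mu[k, ] <- cl$mu; g0[k, ] <- cl$gamma0; g1[k, ] <- cl$gamma1
    alpha[seeds[k], k] <- fit$alpha  # the seed's own ML abundance level
  }
  if (variant == "reduced")
    alpha <- matrix(rep(colMeans(alpha), each = G), G, K)
  hurdle_params(p = rep(1 / K, K), mu = mu, gamma0 = g0, gamma1 = g1,
                alpha = alpha, s = s, variant = variant)
}

# per-feature starting abundance: log mean positive count minus the mean
# normalization factor over the samples where the feature is positive
.alpha_start <- function(counts, s) {
  vapply(seq_len(n_features(counts)), function(g) {
    v <- counts$counts[g, ]
    pos <- v > 0
    if (!any(pos)) return(0)
    log(mean(v[pos])) - mean(s[pos])
  }, numeric(1))
}

# zero-truncated Poisson mean and its derivative, stable near zero
.ztp_mean <- function(lam) ifelse(lam < 1e-8, 1 + lam / 2, lam / -expm1(-lam))
.ztp_mean_d <- function(lam) {
  d <- -expm1(-lam)
  ifelse(lam < 1e-6, 0.5 + lam / 12, (d - lam * (1 - d)) / d^2)
}

# hurdle MLE for one feature. The likelihood separates: the zero part gives
# the clamped Bernoulli MLE for gamma0 per treatment (gamma1 starts at 0),
# and the truncated-Poisson part gives, per treatment with positive counts,
# the offset eta_i = alpha + mu_i solving sum(N - A(exp(s + eta))) = 0.
# Treatments with no positive counts are unidentified in the Poisson part;
# their mu starts at 0, and alpha is the mean of the identified offsets, so
# mu sums to zero by construction.
.single_feature_fit <- function(counts, g, s) {
  ti <- as.integer(counts$treatment)
  I <- nlevels(counts$treatment)
  v <- counts$counts[g, ]
  eta <- rep(NA_real_, I)
  g0 <- numeric(I)
  for (i in seq_len(I)) {
    idx <- which(ti == i)
    pos <- idx[v[idx] > 0]
    g0[i] <- min(12, max(-12, stats::qlogis(length(pos) / length(idx))))
    if (length(pos) == 0) next
    e <- log(mean(v[pos])) - mean(s[pos])
    for (it in 1:40) {
      lam <- exp(s[pos] + e)
      f <- sum(v[pos] - .ztp_mean(lam))
      if (abs(f) < 1e-10) break
      fp <- sum(lam * .ztp_mean_d(lam))
      step <- min(3, max(-3, f / fp))
      e <- min(12, max(-12, e + step))
    }
    eta[i] <- e
  }
  act <- which(!is.na(eta))
  a <- if (length(act) > 0) mean(eta[act]) else 0
  mu <- rep(0, I)
  mu[act] <- eta[act] - a
  list(mu = mu, gamma0 = g0, gamma1 = rep(0, I), alpha = a)
}

#' Multiple-start fitting with Kendall's tau seeding
#'
#' Runs the full pipeline (seed selection, seed MLE initialization, EM or
#' simulated-annealing fit) `n_starts` times and returns the fit with the
#' largest converged log-likelihood. The first start uses the deterministic
#' first-seed rule of [select_seeds]; the remaining starts draw their first
#' seed at random, which diversifies the starting points. Five starts is the
#' default.
#'
#' @inheritParams run_em
#' @param n_starts number of starts (>= 1)
#' @param method `"em"` or `"sa"`
#' @param seed optional integer seed making the randomized starts (and the
#'   SA assignments) reproducible
#' @param s optional precomputed normalization factors
#' @param D optional precomputed [tau_distance_matrix] (saves time when
#'   fitting the same data at several `K`)
#' @param schedule [anneal_schedule] used when `method = "sa"`
#' @param variant model variant, `"full"` or `"reduced"`
#' @return the best `phclust_fit`, with element `start_logliks` recording
#'   every start's final log-likelihood and `seeds` the seed features used
#'   by the winning start
#' @export
multi_start <- function(counts, K, n_starts = 5, method = c("em", "sa"),
                        seed = NULL, s = NULL, D = NULL,
                        schedule = anneal_schedule(), tol = 1e-6,
                        max_iter = 200, variant = c("full", "reduced"),
                        verbose = FALSE) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  stopifnot(n_starts >= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- with_lfact(counts)
  if (is.null(s)) s <- upper_quartile_factors(counts)
  if (is.null(D) && K > 1) D <- tau_distance_matrix(counts)
  G <- n_features(counts)
  best <- NULL
  lls <- numeric(n_starts)
  for (r in seq_len(n_starts)) {
    first <- if (r == 1) NULL else sample.int(G, 1)
    seeds <- if (K == 1) {
      if (is.null(first)) which.max(rowSums(counts$counts)) else first
    } else {
      select_seeds(D, K, counts = counts, first_seed = first)
    }
    init <- params_from_seeds(counts, seeds, s = s, variant = variant)
    fit <- if (method == "em") {
      run_em(counts, K, init, tol = tol, max_iter = max_iter,
             verbose = verbose)
    } else {
      run_sa(counts, K, init, schedule = schedule, tol = tol,
             max_iter = max_iter, verbose = verbose)
    }
    lls[r] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$seeds <- seeds
    }
  }
  best$start_logliks <- lls
  best
}
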