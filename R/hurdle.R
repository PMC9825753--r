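#' Poisson hurdle log probability mass function
#'
#' The hurdle model places probability `1 - q` on zero and distributes the
#' remaining mass `q` over the positive integers via a zero-truncated Poisson
#' with (pre-truncation) mean `lam`:
#' `P(n) = q * lam^n * exp(-lam) / (n! * (1 - exp(-lam)))` for `n > 0`.
#'
#' @param n non-negative integer count(s)
#' @param lam positive Poisson mean(s) before truncation
#' @param q probability of a positive count, in `[0, 1]`
#' @return log probability; `-Inf` at boundaries (e.g. `q = 0` with `n > 0`)
#' @examples
#' hurdle_log_pmf(0, 5, 0.3)  # log(0.7)
#' sum(exp(hurdle_log_pmf(0:200, 2, 0.6)))  # 1
#' @export
hurdle_log_pmf <- function(n, lam, q) {
  m <- max(length(n), length(lam), length(q))
  n <- rep_len(n, m); lam <- rep_len(lam, m); q <- rep_len(q, m)
  if (any(!is.finite(n)) || any(n < 0) || any(n != round(n)))
    stop("n must be non-negative integers")
  if (any(lam <= 0)) stop("lam must be positive")
  if (any(q < 0 | q > 1)) stop("q must be in [0, 1]")
  out <- numeric(m)
  z <- n == 0
  out[z] <- log1p(-q[z])
  if (any(!z)) {
    i <- !z
    out[i] <- log(q[i]) - log1mexp(lam[i]) +
      n[i] * log(lam[i]) - lam[i] - lgamma(n[i] + 1)
  }
  out
}

# log(1 - exp(-lam)), stable (vectorized R twin of the C++ helper)
log1mexp <- function(lam) {
  out <- numeric(length(lam))
  big <- lam > log(2)
  out[big] <- log1p(-exp(-lam[big]))
  out[!big] <- log(-expm1(-lam[!big]))
  out
}

#' Per-cluster hurdle parameters
#'
#' Parameters shared by all features of one mixture component: treatment
#' effects `mu` (log scale, sum-to-zero), the logistic zero-part coefficients
#' `gamma0` (intercept) and `gamma1` (non-negative slope on the normalization
#' factor), one pair per treatment, and the mixing proportion `p`.
#'
#' @param mu numeric length-`I`, must sum to 0 (tolerance 1e-10)
#' @param gamma0 numeric length-`I`
#' @param gamma1 numeric length-`I`, all `>= 0`
#' @param p mixing proportion in `[0, 1]`
#' @return object of class `cluster_params`
#' @export
cluster_params <- function(mu, gamma0, gamma1, p = 1) {
  if (abs(sum(mu)) > 1e-10) stop("mu must sum to zero")
  if (length(gamma0) != length(mu) || length(gamma1) != length(mu))
    stop("mu, gamma0, gamma1 must have one entry per treatment")
  if (any(gamma1 < 0)) stop("gamma1 must be non-negative")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  structure(list(mu = as.numeric(mu), gamma0 = as.numeric(gamma0),
                 gamma1 = as.numeric(gamma1), p = as.numeric(p)),
            class = "cluster_params")
}

# validation-free twin of cluster_params for the fitting loops, where the
# invariants hold by construction
.cluster_params_fast <- function(mu, gamma0, gamma1, p) {
  structure(list(mu = mu, gamma0 = gamma0, gamma1 = gamma1, p = p),
            class = "cluster_params")
}

#' Full mixture parameter set
#'
#' All parameters of a `K`-component Poisson hurdle mixture over `G` features:
#' per-cluster [cluster_params] stored as matrices, the feature-specific
#' log geometric means `alpha` (`G x K`), and the fixed normalization factors
#' `s`. In the `reduced` variant all features in a cluster share one
#' abundance level, so each column of `alpha` is constant.
#'
#' @param p length-`K` mixing proportions summing to 1
#' @param mu `K x I` treatment effects, each row summing to 0
#' @param gamma0,gamma1 `K x I` logistic coefficients, `gamma1 >= 0`
#' @param alpha `G x K` log geometric abundance means
#' @param s length-`N` normalization factors
#' @param variant `"full"` or `"reduced"`
#' @return object of class `hurdle_params`
#' @export
hurdle_params <- function(p, mu, gamma0, gamma1, alpha, s,
                          variant = c("full", "reduced")) {
  variant <- match.arg(variant)
  p <- as.numeric(p)
  mu <- as.matrix(mu); gamma0 <- as.matrix(gamma0); gamma1 <- as.matrix(gamma1)
  alpha <- as.matrix(alpha)
  K <- length(p)
  if (abs(sum(p) - 1) > 1e-8) stop("mixing proportions must sum to 1")
  if (any(p < 0)) stop("mixing proportions must be non-negative")
  if (nrow(mu) != K || nrow(gamma0) != K || nrow(gamma1) != K ||
      ncol(alpha) != K)
    stop("inconsistent number of clusters across parameter blocks")
  if (max(abs(rowSums(mu))) > 1e-8) stop("each row of mu must sum to zero")
  if (any(gamma1 < 0)) stop("gamma1 must be non-negative")
  if (variant == "reduced" &&
      any(apply(alpha, 2, function(a) diff(range(a))) > 1e-10))
    stop("reduced variant requires constant alpha within each cluster")
  structure(list(p = p, mu = mu, gamma0 = gamma0, gamma1 = gamma1,
                 alpha = alpha, s = as.numeric(s), variant = variant),
            class = "hurdle_params")
}

#' @export
print.hurdle_params <- function(x, ...) {
  cat(sprintf("hurdle_params: K = %d clusters, I = %d treatments, G = %d features (%s variant)\n",
              length(x$p), ncol(x$mu), nrow(x$alpha), x$variant))
  invisible(x)
}

#' @rdname hurdle_params
#' @param params a `hurdle_params` object
#' @param k cluster index
#' @export
get_cluster <- function(params, k) {
  cluster_params(mu = params$mu[k, ], gamma0 = params$gamma0[k, ],
                 gamma1 = params$gamma1[k, ], p = params$p[k])
}

#' Weighted per-cluster log-likelihood
#'
#' Evaluates `l_k = sum_g w_g * log f(N_g | mu_k, gamma_k, alpha_gk)`, the
#' objective maximized for one cluster in the M step, with
#' `log(lambda) = s + alpha + mu` and `q = plogis(gamma0 + gamma1 * s)`.
#'
#' @param counts a [count_matrix]
#' @param weights length-`G` non-negative weights (posterior memberships)
#' @param cluster a [cluster_params]
#' @param alpha_col length-`G` abundance levels for this cluster
#' @param s length-`N` normalization factors
#' @return scalar log-likelihood
#' @export
cluster_loglik <- function(counts, weights, cluster, alpha_col, s) {
  stopifnot(inherits(counts, "count_matrix"),
            length(weights) == n_features(counts),
            length(alpha_col) == n_features(counts),
            length(s) == n_samples(counts))
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  cpp_cluster_loglik(counts$counts, lfact_of(counts), as.numeric(weights),
                     as.numeric(s), treat_index0(counts),
                     as.numeric(alpha_col), cluster$mu,
                     cluster$gamma0, cluster$gamma1)
}

#' One-step update of the zero-part logistic coefficients
#'
#' One guarded Newton pass over `(gamma0_i, gamma1_i)` for each treatment,
#' maximizing the zero-part of the weighted cluster log-likelihood. The step
#' is halved until the objective does not decrease (at most `max_halvings`
#' halvings, after which the current value is kept). `gamma1` is projected to
#' `>= 0` and `gamma0` clamped to `[-12, 12]`, which keeps fitted positive
#' probabilities away from exact 0/1 when a cluster-treatment cell is all-zero
#' or all-positive.
#'
#' @inheritParams cluster_loglik
#' @param max_halvings maximum step halvings in the ascent guard
#' @return updated [cluster_params]
#' @export
update_gamma <- function(counts, weights, cluster, s, max_halvings = 20) {
  up <- cpp_update_gamma(counts$counts, as.numeric(weights), as.numeric(s),
                         treat_index0(counts), cluster$gamma0, cluster$gamma1,
                         as.integer(max_halvings))
  .cluster_params_fast(cluster$mu, up$gamma0, up$gamma1, cluster$p)
}

#' One-step update of abundance levels and treatment effects
#'
#' One guarded coordinate-ascent pass for the truncated-Poisson part of the
#' weighted cluster log-likelihood: first a Newton step for each `alpha_gk`
#' (features with at least one positive count and positive weight; others
#' retain their value and contribute only through the zero part), then a
#' Newton step for each treatment effect `mu_ki`. `mu` is re-centered to sum
#' to zero with the shift absorbed into `alpha`, which leaves the likelihood
#' unchanged. Every step is halved until the objective does not decrease, so
#' the cluster log-likelihood never drops (the generalized-EM contract).
#'
#' @inheritParams update_gamma
#' @param alpha_col length-`G` abundance levels for this cluster
#' @param variant `"full"` (feature-specific alpha) or `"reduced"` (one
#'   shared abundance level per cluster)
#' @return list with updated `cluster` and `alpha_col`
#' @export
update_alpha_mu <- function(counts, weights, cluster, alpha_col, s,
                            variant = "full", max_halvings = 20) {
  if (!variant %in% c("full", "reduced")) stop("unknown variant")
  w <- as.numeric(weights)
  tr <- treat_index0(counts)
  s <- as.numeric(s)
  if (variant == "full") {
    alpha_col <- cpp_update_alpha(counts$counts, w, s, tr,
                                  as.numeric(alpha_col), cluster$mu,
                                  as.integer(max_halvings))
  } else {
    # shared alpha_k: scalar ascent, realised as a single-group "mu" update
    # with the treatment effects folded into the sample offsets
    a_k <- alpha_col[1]
    s_eff <- s + cluster$mu[as.integer(counts$treatment)]
    a_new <- cpp_update_mu(counts$counts, w, s_eff,
                           integer(n_samples(counts)),
                           rep(0, n_features(counts)),
                           a_k, as.integer(max_halvings))
    alpha_col <- rep(a_new[1], n_features(counts))
  }
  mu <- cpp_update_mu(counts$counts, w, s, tr, as.numeric(alpha_col),
                      cluster$mu, as.integer(max_halvings))
  shift <- mean(mu)
  mu <- mu - shift
  alpha_col <- alpha_col + shift
  list(cluster = .cluster_params_fast(mu, cluster$gamma0, cluster$gamma1,
                                      cluster$p),
       alpha_col = alpha_col)
}
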