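#' Merge the closest pair of clusters
#'
#' Evaluates every pair of clusters by pooling their posterior mass, refitting
#' the pooled cluster's parameters with a few one-step updates, and measuring
#' the resulting drop in total mixture log-likelihood. The pair with the
#' smallest drop is merged and the reduced `K - 1` model is polished by a
#' short EM run from the pooled parameters.
#'
#' @param counts a [count_matrix]
#' @param result a converged `phclust_fit` with `K >= 2` clusters
#' @param polish_iter maximum EM iterations for the post-merge polish
#' @param tol EM tolerance for the polish
#' @return list with `result` (the polished `K - 1` fit), `pair` (the merged
#'   cluster indices) and `delta_loglik` (log-likelihood lost by the merge,
#'   measured against `result$loglik` before polishing)
#' @export
merge_once <- function(counts, result, polish_iter = 20, tol = 1e-6) {
  params <- result$params
  K <- length(params$p)
  if (K < 2) stop("need at least two clusters to merge")
  counts <- with_lfact(counts)
  Z <- result$posterior
  L <- .loglik_matrix(counts, params)
  best <- NULL
  for (a in seq_len(K - 1)) {
    for (b in (a + 1):K) {
      cand <- .merge_candidate(counts, params, Z, L, a, b)
      if (is.null(best) || cand$loglik > best$loglik) {
        best <- cand
        best$pair <- c(a, b)
      }
    }
  }
  delta <- result$loglik - best$loglik
  polished <- run_em(counts, K - 1, best$params, tol = tol,
                     max_iter = polish_iter)
  list(result = polished, pair = best$pair, delta_loglik = delta)
}

# build and score one merged-pair candidate: pooled weights, pooled starting
# parameters, two one-step refinement passes on the merged cluster only
.merge_candidate <- function(counts, params, Z, L, a, b, passes = 2) {
  w <- Z[, a] + Z[, b]
  p_ab <- params$p[a] + params$p[b]
  lead <- if (params$p[a] >= params$p[b]) a else b
  wa <- params$p[a] / p_ab
  cl <- cluster_params(mu = wa * params$mu[a, ] + (1 - wa) * params$mu[b, ],
                       gamma0 = params$gamma0[lead, ],
                       gamma1 = params$gamma1[lead, ],
                       p = min(1, p_ab))
  denom <- pmax(w, 1e-12)
  alpha_col <- (Z[, a] * params$alpha[, a] + Z[, b] * params$alpha[, b]) / denom
  alpha_col[w < 1e-12] <- 0.5 * (params$alpha[w < 1e-12, a] +
                                   params$alpha[w < 1e-12, b])
  for (it in seq_len(passes)) {
    cl <- update_gamma(counts, w, cl, params$s)
    up <- update_alpha_mu(counts, w, cl, alpha_col, params$s,
                          variant = params$variant)
    cl <- up$cluster; alpha_col <- up$alpha_col
  }
  keep <- setdiff(seq_along(params$p), c(a, b))
  p_new <- c(params$p[keep], p_ab)
  p_new <- p_new / sum(p_new)
  merged <- hurdle_params(p = p_new,
                          mu = rbind(params$mu[keep, , drop = FALSE], cl$mu),
                          gamma0 = rbind(params$gamma0[keep, , drop = FALSE],
                                         cl$gamma0),
                          gamma1 = rbind(params$gamma1[keep, , drop = FALSE],
                                         cl$gamma1),
                          alpha = cbind(params$alpha[, keep, drop = FALSE],
                                        alpha_col),
                          s = params$s, variant = params$variant)
  Lm <- cbind(L[, keep, drop = FALSE],
              .cluster_col(counts, alpha_col, cl, params$s))
  list(params = merged,
       loglik = .estep(counts, Lm, p_new)$loglik)
}

# log-density column for a single cluster
.cluster_col <- function(counts, alpha_col, cl, s) {
  cpp_loglik_matrix(counts$counts, lfact_of(counts), s, treat_index0(counts),
                    matrix(alpha_col, ncol = 1), matrix(cl$mu, nrow = 1),
                    matrix(cl$gamma0, nrow = 1), matrix(cl$gamma1, nrow = 1))
}

#' Likelihood ratio stopping rule for cluster merging
#'
#' Refers `2 * (loglik_full - loglik_merged)` to a chi-square distribution
#' whose degrees of freedom count the cluster-level parameters eliminated by
#' the merge: `(I - 1)` treatment effects, `2 I` logistic coefficients and
#' one mixing proportion. The merge is rejected (merging stops) when the
#' upper-tail p-value falls below `alpha`.
#'
#' @param loglik_full log-likelihood of the larger (K-cluster) model
#' @param loglik_merged log-likelihood after the merge (K - 1 clusters)
#' @param df degrees of freedom; use `(I - 1) + 2 * I + 1`
#' @param alpha significance level (default 0.05)
#' @return list with `statistic`, `df`, `p_value` and `stop` (TRUE when the
#'   merge is rejected and merging should halt)
#' @export
lrt_stop <- function(loglik_full, loglik_merged, df, alpha = 0.05) {
  if (loglik_full < loglik_merged - 1e-2)
    warning("merged model log-likelihood exceeds the full model's; ",
            "the larger model was likely not converged")
  stat <- max(0, 2 * (loglik_full - loglik_merged))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p, stop = p < alpha)
}

#' Choose the number of clusters by hierarchical merging with LRTs
#'
#' Fits the mixture at `k_max` clusters with [multi_start], then repeatedly
#' merges the closest pair of clusters ([merge_once]), testing each merge
#' with [lrt_stop]. The selected `K*` is the number of clusters right before
#' the first rejected merge; if no merge is ever rejected, `K* = 1`.
#'
#' The degrees of freedom per merge depend on `df_method`. The default,
#' `"mixture"`, counts every parameter the merge removes -- the eliminated
#' cluster's `(I - 1)` treatment effects, `2 I` logistic coefficients and one
#' mixing proportion, plus one abundance level `alpha` for each feature
#' currently assigned to the merged pair (those features lose one fitted
#' abundance parameter) -- and doubles the total, the classical adjustment
#' for the nonstandard null distribution of mixture likelihood ratio tests,
#' where the naive chi-square is known to be anti-conservative.
#' `"cluster"` uses only the `(I - 1) + 2 I + 1` cluster-level parameters.
#'
#' @inheritParams multi_start
#' @param k_max largest number of clusters considered (>= 2)
#' @param alpha LRT significance level
#' @param fit optional precomputed `phclust_fit` at `k_max` (skips the
#'   initial multi-start fit)
#' @param polish_iter EM iterations used to polish each merged model
#' @param df_method `"mixture"` (default) or `"cluster"`, see Details
#' @return list with `K` (the selected number of clusters), `result` (the
#'   fit at `K`), and `path` (a data frame tracing each merge: `K`, merged
#'   pair, log-likelihoods, LRT statistic, df, p-value)
#' @export
choose_k <- function(counts, k_max = 15, alpha = 0.05, n_starts = 5,
                     seed = NULL, method = c("em", "sa"), s = NULL, D = NULL,
                     fit = NULL, polish_iter = 20, tol = 1e-6,
                     max_iter = 200, df_method = c("mixture", "cluster"),
                     verbose = FALSE) {
  method <- match.arg(method)
  df_method <- match.arg(df_method)
  stopifnot(k_max >= 2)
  counts <- with_lfact(counts)
  if (is.null(fit))
    fit <- multi_start(counts, k_max, n_starts = n_starts, method = method,
                       seed = seed, s = s, D = D, tol = tol,
                       max_iter = max_iter, verbose = verbose)
  I <- nlevels(counts$treatment)
  df_cluster <- (I - 1) + 2 * I + 1
  path <- list()
  current <- fit
  selected <- NULL
  while (length(current$params$p) >= 2) {
    m <- merge_once(counts, current, polish_iter = polish_iter, tol = tol)
    df <- if (df_method == "cluster") df_cluster else {
      n_pair <- sum(current$assignments %in% m$pair)
      2 * (df_cluster + n_pair)
    }
    test <- lrt_stop(current$loglik, m$result$loglik, df = df, alpha = alpha)
    path[[length(path) + 1]] <- data.frame(
      K = length(current$params$p),
      merged_a = m$pair[1], merged_b = m$pair[2],
      loglik_full = current$loglik, loglik_merged = m$result$loglik,
      statistic = test$statistic, df = test$df, p_value = test$p_value,
      rejected = test$stop)
    if (test$stop) {
      selected <- current
      break
    }
    current <- m$result
  }
  if (is.null(selected)) selected <- current  # merged all the way to K = 1
  list(K = length(selected$params$p), result = selected,
       path = do.call(rbind, path))
}

#' Information criteria for a fitted mixture
#'
#' `AIC = -2 loglik + 2 npar` and `BIC = -2 loglik + log(n) npar`, where the
#' parameter count is `K ((I - 1) + 2 I + 1) - 1` cluster-level parameters
#' plus one free abundance level per (feature with any positive count) per
#' cluster (`K` abundance levels in total for the reduced variant). The BIC
#' sample size defaults to the number of features, the independent units of
#' the mixture; `bic_n = "cells"` uses `G * N` instead.
#'
#' @param result a converged `phclust_fit`
#' @param counts the [count_matrix] it was fitted to
#' @param bic_n `"features"` (n = G, default) or `"cells"` (n = G * N)
#' @return named numeric vector with elements `AIC`, `BIC`, `npar`
#' @export
aic_bic <- function(result, counts, bic_n = c("features", "cells")) {
  bic_n <- match.arg(bic_n)
  params <- result$params
  K <- length(params$p)
  I <- nlevels(counts$treatment)
  G <- n_features(counts)
  n_pos <- sum(rowSums(counts$counts > 0) > 0)
  free_alpha <- if (params$variant == "full") K * n_pos else K
  npar <- K * ((I - 1) + 2 * I + 1) - 1 + free_alpha
  n <- if (bic_n == "features") G else G * n_samples(counts)
  c(AIC = -2 * result$loglik + 2 * npar,
    BIC = -2 * result$loglik + log(n) * npar,
    npar = npar)
}

#' Fit a range of cluster numbers and tabulate information criteria
#'
#' Convenience scan for AIC/BIC-based selection: fits the mixture at each
#' `K = 1, ..., k_max` with [multi_start] and reports the log-likelihood,
#' parameter count and both criteria.
#'
#' @inheritParams choose_k
#' @param keep_fits return the fitted objects as well
#' @return data frame with columns `K`, `loglik`, `npar`, `AIC`, `BIC`; if
#'   `keep_fits` is TRUE, the fits are attached as attribute `"fits"`
#' @export
ic_scan <- function(counts, k_max = 15, n_starts = 5, seed = NULL,
                    method = c("em", "sa"), tol = 1e-6, max_iter = 200,
                    keep_fits = FALSE, verbose = FALSE) {
  method <- match.arg(method)
  counts <- with_lfact(counts)
  s <- upper_quartile_factors(counts)
  D <- tau_distance_matrix(counts)
  fits <- vector("list", k_max)
  rows <- vector("list", k_max)
  for (K in seq_len(k_max)) {
    fit <- multi_start(counts, K, n_starts = n_starts, method = method,
                       seed = if (is.null(seed)) NULL else seed + K,
                       s = s, D = D, tol = tol, max_iter = max_iter,
                       verbose = verbose)
    ic <- aic_bic(fit, counts)
    rows[[K]] <- data.frame(K = K, loglik = fit$loglik, npar = ic["npar"],
                            AIC = ic["AIC"], BIC = ic["BIC"])
    if (keep_fits) fits[[K]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_fits) attr(out, "fits") <- fits
  out
}
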