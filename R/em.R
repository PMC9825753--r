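#' E step: posterior cluster membership probabilities
#'
#' Computes `Z_gk`, the conditional probability that feature `g` belongs to
#' cluster `k` given the current parameters, proportional to
#' `p_k * f(N_g | alpha_gk, mu_k, gamma_k)`. All work is done in log space
#' with a row-wise log-sum-exp, so very small densities do not underflow.
#'
#' @param counts a [count_matrix]
#' @param params a [hurdle_params]
#' @return `G x K` posterior matrix, rows summing to 1, with attribute
#'   `"loglik"` holding the total mixture log-likelihood at `params`
#' @export
e_step <- function(counts, params) {
  es <- .estep(counts, .loglik_matrix(counts, params), params$p)
  Z <- es$Z
  attr(Z, "loglik") <- es$loglik
  Z
}

# log f(N_g | cluster k) for all g, k
.loglik_matrix <- function(counts, params) {
  cpp_loglik_matrix(counts$counts, lfact_of(counts), params$s,
                    treat_index0(counts), params$alpha, params$mu,
                    params$gamma0, params$gamma1)
}

# shared posterior/log-likelihood computation given the density matrix
.estep <- function(counts, L, p, temp = 1) {
  out <- cpp_posterior(L, log(p), temp)
  if (out$degenerate)
    stop("a feature has zero density under every cluster")
  out
}

#' M step: closed-form mixing proportions plus one-step parameter updates
#'
#' Updates `p_k = mean_g(Z_gk)` exactly, then applies the one-step
#' coordinate-ascent updates ([update_gamma] then [update_alpha_mu]) to every
#' cluster with the posterior column as weights. Because each one-step update
#' never decreases the weighted cluster log-likelihood, the total mixture
#' log-likelihood never decreases across an E/M cycle (generalized EM).
#'
#' @inheritParams e_step
#' @param Z `G x K` posterior matrix (rows sum to 1)
#' @return updated [hurdle_params]
#' @export
m_step <- function(counts, Z, params) {
  if (params$variant == "full") {
    up <- cpp_m_step(counts$counts, lfact_of(counts), params$s,
                     treat_index0(counts), Z, params$alpha, params$mu,
                     params$gamma0, params$gamma1, 20L, 1e-16)
    return(structure(list(p = up$p, mu = up$mu, gamma0 = up$gamma0,
                          gamma1 = up$gamma1, alpha = up$alpha,
                          s = params$s, variant = params$variant),
                     class = "hurdle_params"))
  }
  .m_step_r(counts, Z, params)
}

# reference implementation: chain the exported one-step updates per cluster
.m_step_r <- function(counts, Z, params) {
  K <- length(params$p)
  p <- colMeans(Z)
  mu <- params$mu; g0 <- params$gamma0; g1 <- params$gamma1
  alpha <- params$alpha
  for (k in seq_len(K)) {
    wk <- Z[, k]
    # posterior mass this small cannot move l_k beyond the monotonicity
    # slack; dropping it lets the updates skip unrelated features entirely
    wk[wk < 1e-16] <- 0
    cl <- .cluster_params_fast(mu[k, ], g0[k, ], g1[k, ], p[k])
    cl <- update_gamma(counts, wk, cl, params$s)
    up <- update_alpha_mu(counts, wk, cl, alpha[, k], params$s,
                          variant = params$variant)
    mu[k, ] <- up$cluster$mu
    g0[k, ] <- up$cluster$gamma0
    g1[k, ] <- up$cluster$gamma1
    alpha[, k] <- up$alpha_col
  }
  hurdle_params(p = p, mu = mu, gamma0 = g0, gamma1 = g1, alpha = alpha,
                s = params$s, variant = params$variant)
}

#' Fit a Poisson hurdle mixture by generalized EM
#'
#' Iterates [e_step] and [m_step] from a given initialization until the
#' relative change in total log-likelihood falls below `tol` or `max_iter`
#' iterations are reached. Features are hard-assigned to the cluster with the
#' largest final posterior (ties broken by the lowest cluster index). If a
#' cluster empties out (posterior mass below 1e-8), it is re-seeded from the
#' feature with the lowest maximum posterior rather than aborting, so that
#' downstream model-size selection can rely on stable fits.
#'
#' @inheritParams e_step
#' @param K number of clusters (must match `init`)
#' @param init a [hurdle_params] with `K` clusters (see [params_from_seeds])
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter maximum number of EM iterations
#' @param verbose print the per-iteration log-likelihood
#' @return object of class `phclust_fit`: list with `assignments`, `params`,
#'   `posterior`, `loglik`, `loglik_trace`, `converged`, `n_iter`
#' @examples
#' sim <- simulate_dataset(simulation_config(G = 60, K = 2, seed = 1))
#' fit <- multi_start(sim$counts, K = 2, n_starts = 2, seed = 1)
#' table(fit$assignments, sim$labels)
#' @export
run_em <- function(counts, K, init, tol = 1e-6, max_iter = 200,
                   verbose = FALSE) {
  stopifnot(K >= 1, length(init$p) == K)
  counts <- with_lfact(counts)
  params <- init
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0
  Z <- NULL
  repeat {
    iter <- iter + 1
    L <- .loglik_matrix(counts, params)
    es <- .estep(counts, L, params$p)
    Z <- es$Z
    trace <- c(trace, es$loglik)
    if (verbose)
      message(sprintf("iter %d loglik %.6f", iter, es$loglik))
    if (is.finite(ll_prev) &&
        abs(es$loglik - ll_prev) / (abs(es$loglik) + 1) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- es$loglik
    Z <- .reseed_empty(Z)
    params <- m_step(counts, Z, params)
  }
  .finish_fit(Z, params, trace, converged, iter)
}

# re-seed empty clusters from the most ambiguous features (one distinct
# feature per empty cluster; a bounded number of rounds in case moving a
# feature empties yet another cluster)
.reseed_empty <- function(Z) {
  for (round in 1:5) {
    mass <- colSums(Z)
    empty <- which(mass < 1e-8)
    if (length(empty) == 0) break
    ord <- order(apply(Z, 1, max))[seq_along(empty)]
    for (j in seq_along(empty)) {
      Z[ord[j], ] <- 0
      Z[ord[j], empty[j]] <- 1
    }
  }
  Z
}

.finish_fit <- function(Z, params, trace, converged, iter) {
  structure(list(assignments = max.col(Z, ties.method = "first"),
                 params = params,
                 posterior = Z,
                 loglik = trace[length(trace)],
                 loglik_trace = trace,
                 converged = converged,
                 n_iter = iter),
            class = "phclust_fit")
}

#' @export
print.phclust_fit <- function(x, ...) {
  cat(sprintf("phclust_fit: K = %d, loglik = %.3f, %d iterations (%s)\n",
              length(x$params$p), x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat("cluster sizes:", table(factor(x$assignments,
                                     levels = seq_along(x$params$p))), "\n")
  invisible(x)
}

#' Total mixture log-likelihood at a parameter set
#'
#' @inheritParams e_step
#' @return scalar log-likelihood `sum_g log sum_k p_k f(N_g | k)`
#' @export
total_loglik <- function(counts, params) {
  .estep(counts, .loglik_matrix(counts, params), params$p)$loglik
}
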