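#' Geometric cooling schedule for simulated annealing
#'
#' @param t0 initial temperature (> 0); default 2
#' @param c cooling rate in (0, 1); default 0.9, so `t(m) = t0 * c^m`
#' @param t_min temperature below which the run switches to deterministic EM
#' @return object of class `anneal_schedule`
#' @export
anneal_schedule <- function(t0 = 2, c = 0.9, t_min = 0.01) {
  stopifnot(t0 > 0, c > 0, c < 1, t_min > 0)
  structure(list(t0 = t0, c = c, t_min = t_min), class = "anneal_schedule")
}

#' Tempered posterior membership probabilities
#'
#' Raises each mixture component's contribution to the power `1/t` before
#' normalizing: `Z~_gk = (p_k f_gk)^(1/t) / sum_l (p_l f_gl)^(1/t)`.
#' At `t = 1` this is exactly the [e_step] posterior; large `t` flattens the
#' rows towards uniform, small `t` sharpens them towards one-hot.
#'
#' @inheritParams e_step
#' @param t positive temperature
#' @return `G x K` matrix, rows summing to 1
#' @export
tempered_posterior <- function(counts, params, t) {
  stopifnot(t > 0)
  L <- .loglik_matrix(counts, params)
  .estep(counts, L, params$p, temp = t)$Z
}

#' Multinomial hard assignment from tempered posteriors
#'
#' Draws, independently for each feature, a one-hot cluster indicator with
#' row probabilities `ztilde`, producing the 0/1 matrix that replaces the
#' posterior in the simulated-annealing M step. Uses R's current RNG stream,
#' so results are reproducible under `set.seed()`.
#'
#' @param ztilde `G x K` matrix with rows summing to 1
#' @return `G x K` 0/1 matrix with exactly one 1 per row
#' @export
sa_assign <- function(ztilde) {
  G <- nrow(ztilde); K <- ncol(ztilde)
  cum <- t(apply(ztilde, 1, cumsum))
  u <- stats::runif(G) * cum[, K]  # guard rounding in the row totals
  idx <- rowSums(u > cum) + 1L
  idx[idx > K] <- K
  ind <- matrix(0, G, K)
  ind[cbind(seq_len(G), idx)] <- 1
  ind
}

#' Fit a Poisson hurdle mixture by simulated-annealing EM
#'
#' Replaces the E step by a stochastic one: tempered posteriors
#' ([tempered_posterior]) are drawn into hard one-hot assignments
#' ([sa_assign]) that feed the usual M step, while the temperature cools
#' geometrically from `t0` by factor `c` each iteration. The added randomness
#' lets the fit escape local maxima early on. Once the temperature drops
#' below `t_min`, the run finishes with deterministic EM iterations until the
#' [run_em] convergence rule fires, so the reported endpoint is a fixed point
#' comparable across methods.
#'
#' @inheritParams run_em
#' @param schedule an [anneal_schedule]
#' @param seed optional integer seed for the stochastic assignments
#' @return a `phclust_fit` (see [run_em]) with extra element `sa_iters`,
#'   the number of stochastic iterations before the EM phase
#' @export
run_sa <- function(counts, K, init, schedule = anneal_schedule(),
                   tol = 1e-6, max_iter = 200, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(schedule, "anneal_schedule"), K >= 1,
            length(init$p) == K)
  if (!is.null(seed)) set.seed(seed)
  counts <- with_lfact(counts)
  params <- init
  trace <- numeric(0)
  t <- schedule$t0
  iter <- 0
  while (t >= schedule$t_min && iter < max_iter) {
    iter <- iter + 1
    L <- .loglik_matrix(counts, params)
    trace <- c(trace, .estep(counts, L, params$p)$loglik)
    ztilde <- .estep(counts, L, params$p, temp = t)$Z
    ind <- sa_assign(ztilde)
    ind <- .reseed_empty(ind)
    params <- m_step(counts, ind, params)
    if (verbose)
      message(sprintf("SA iter %d t %.4f loglik %.6f", iter, t,
                      trace[length(trace)]))
    t <- schedule$c * t
  }
  em <- run_em(counts, K, params, tol = tol,
               max_iter = max(1, max_iter - iter), verbose = verbose)
  em$loglik_trace <- c(trace, em$loglik_trace)
  em$n_iter <- iter + em$n_iter
  em$sa_iters <- iter
  em
}
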