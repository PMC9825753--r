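#' Log upper-quartile normalization factors
#'
#' Computes the per-sample sequencing-depth offsets `s` used in the Poisson
#' mean: the log of the 75th percentile of each sample's *nonzero* counts,
#' centered so the factors sum to zero across samples. Centering identifies
#' the additive decomposition `log(lambda) = s + alpha + mu`.
#'
#' @param x a [count_matrix] or a plain count matrix (features in rows).
#' @return Named numeric vector of length `N` (log scale, sums to 0).
#' @examples
#' x <- count_matrix(matrix(c(0, 4, 4, 0, 16, 16), 3, 2), c("a", "a"))
#' upper_quartile_factors(x)  # (-log(2)/... centered)
#' @export
upper_quartile_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  uq <- vapply(seq_len(ncol(counts)), function(n) {
    v <- counts[, n]
    v <- v[v > 0]
    if (length(v) == 0L)
      stop(sprintf("sample '%s' has no nonzero counts; cannot normalize",
                   colnames(counts)[n] %||% as.character(n)))
    stats::quantile(v, 0.75, type = 7, names = FALSE)
  }, numeric(1))
  s <- log(uq)
  s <- s - mean(s)
  names(s) <- colnames(counts)
  s
}
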