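#' Clustering purity
#'
#' Fraction of features lying in the dominant true class of their predicted
#' cluster: `(1/G) sum_k max_j |pred cluster k intersect true class j|`.
#' Purity is relabeling-invariant but, unlike ARI and NMI, not symmetric in
#' its arguments: it measures how pure the *predicted* clusters are.
#'
#' @param pred,truth equal-length label vectors (any label type)
#' @return value in `[0, 1]`; 1 iff every predicted cluster is pure
#' @export
purity <- function(pred, truth) {
  tab <- .contingency(pred, truth)
  sum(apply(tab, 1, max)) / sum(tab)
}

.contingency <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  table(pred = as.vector(pred), truth = as.vector(truth))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance:
#' `(Index - E[Index]) / (Max - E[Index])` over the `choose(G, 2)` feature
#' pairs. Symmetric, relabeling-invariant, equal to 1 iff the partitions are
#' identical up to relabeling; independent random partitions score about 0.
#'
#' @inheritParams purity
#' @return value `<= 1`
#' @export
adjusted_rand_index <- function(pred, truth) {
  tab <- .contingency(pred, truth)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions degenerate
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' Mutual information between the two partitions normalized to `[0, 1]`.
#' The default normalizer is the geometric mean of the two entropies;
#' `"mean"` (arithmetic) and `"max"` are available as options. Natural
#' logarithms are used throughout (the base cancels). If either partition is
#' degenerate (a single cluster), MI is zero and the NMI is defined as 0,
#' except when both partitions are the identical single-cluster partition
#' (agreement is perfect, returns 1).
#'
#' @inheritParams purity
#' @param normalizer `"sqrt"`, `"mean"` or `"max"`
#' @return value in `[0, 1]`
#' @export
nmi <- function(pred, truth, normalizer = c("sqrt", "mean", "max")) {
  normalizer <- match.arg(normalizer)
  tab <- .contingency(pred, truth)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) {
    return(if (hx == 0 && hy == 0) 1 else 0)
  }
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  denom <- switch(normalizer,
                  sqrt = sqrt(hx * hy),
                  mean = (hx + hy) / 2,
                  max = max(hx, hy))
  min(1, max(0, mi / denom))
}
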