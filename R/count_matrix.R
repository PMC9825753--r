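#' Feature-by-sample count matrix with treatment structure
#'
#' Container for a microbiome feature table: a `G x N` matrix of non-negative
#' integer read counts (features in rows) together with the treatment label of
#' each sample. This is the input object of every clustering function in the
#' package.
#'
#' @param counts numeric or integer matrix, `G` features by `N` samples, all
#'   entries non-negative integers. Row and column names, if present, are used
#'   as feature and sample identifiers.
#' @param treatment vector of length `N` giving the treatment group of each
#'   sample; coerced to a factor. Every level must have at least one sample.
#' @param feature_ids,sample_ids optional character identifiers; default to the
#'   dimnames of `counts` or generated names.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix with dimnames), `treatment` (factor of length `N`).
#' @examples
#' x <- count_matrix(matrix(rpois(20, 3), 4, 5), rep(c("a", "b"), c(2, 3)))
#' n_treatments(x)
#' @export
count_matrix <- function(counts, treatment, feature_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L || nrow(counts) < 1L || ncol(counts) < 2L)
    stop("counts must have at least 1 feature and 2 samples")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (length(treatment) != ncol(counts))
    stop("treatment must have one label per sample")
  treatment <- factor(treatment)
  treatment <- droplevels(treatment)
  if (is.null(feature_ids))
    feature_ids <- rownames(counts) %||% sprintf("f%d", seq_len(nrow(counts)))
  if (is.null(sample_ids))
    sample_ids <- colnames(counts) %||% sprintf("s%d", seq_len(ncol(counts)))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids")
  dimnames(counts) <- list(feature_ids, sample_ids)
  structure(list(counts = counts, treatment = treatment),
            class = "count_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples, %d treatment group(s)\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$treatment)))
  cat(sprintf("zero fraction: %.3f\n", mean(x$counts == 0)))
  invisible(x)
}

#' @rdname count_matrix
#' @param x a `count_matrix`
#' @export
n_features <- function(x) nrow(x$counts)

#' @rdname count_matrix
#' @export
n_samples <- function(x) ncol(x$counts)

#' @rdname count_matrix
#' @export
n_treatments <- function(x) nlevels(x$treatment)

# 0-based treatment index per sample, for the compiled kernels
treat_index0 <- function(x) as.integer(x$treatment) - 1L

# cached lgamma(counts + 1), recomputed lazily and memoised on the object
lfact_of <- function(x) {
  lf <- attr(x, "lfact")
  if (is.null(lf)) lf <- lgamma(x$counts + 1)
  lf
}

# attach the lgamma cache (used by the fitting loops to avoid recomputation)
with_lfact <- function(x) {
  if (is.null(attr(x, "lfact"))) attr(x, "lfact") <- lgamma(x$counts + 1)
  x
}
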