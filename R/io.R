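#' Read a count matrix and treatment map from TSV files
#'
#' The count file has a first column of feature identifiers, a header row of
#' sample identifiers and integer cells. The treatment map is a two-column
#' TSV (sample id, treatment label) covering every sample; samples are
#' reordered by (treatment, order within file).
#'
#' @param path count TSV path
#' @param treatments_path treatment-map TSV path
#' @return a [count_matrix]
#' @export
read_counts <- function(path, treatments_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("count file needs a feature-id column and >= 2 samples")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate feature id '%s'", ids[duplicated(ids)][1]))
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!apply(raw[, -1, drop = FALSE], 2,
                        function(v) all(grepl("^\\s*-?\\d+\\s*$", v))))
    stop(sprintf("non-integer cell in column '%s'",
                 colnames(raw)[-1][bad[1]]))
  }
  if (any(mat != round(mat)))
    stop("non-integer count cell")
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative count for feature '%s', sample '%s'",
                 ids[neg[1, 1]], colnames(mat)[neg[1, 2]]))
  tm <- utils::read.delim(treatments_path, stringsAsFactors = FALSE)
  if (ncol(tm) < 2) stop("treatment map needs two columns: sample, treatment")
  missing <- setdiff(colnames(mat), as.character(tm[[1]]))
  if (length(missing) > 0)
    stop(sprintf("sample '%s' missing from treatment map", missing[1]))
  trt <- tm[[2]][match(colnames(mat), tm[[1]])]
  ord <- order(factor(trt), seq_along(trt))
  count_matrix(mat[, ord, drop = FALSE], trt[ord], feature_ids = ids)
}

#' Write a count matrix (and its treatment map) to TSV
#'
#' @param x a [count_matrix]
#' @param path count TSV path
#' @param treatments_path optional treatment-map TSV path
#' @param id_column name for the feature-id column
#' @return invisibly, `x`
#' @export
write_counts <- function(x, path, treatments_path = NULL,
                         id_column = "feature_id") {
  df <- data.frame(id = rownames(x$counts), x$counts, check.names = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(treatments_path)) {
    tm <- data.frame(sample = colnames(x$counts),
                     treatment = as.character(x$treatment))
    utils::write.table(tm, treatments_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Serialize fitted mixture parameters to JSON
#'
#' Writes per-cluster `p`, `mu`, `gamma0`, `gamma1`, the `alpha` matrix, the
#' normalization factors `s` and the model variant; [read_params_json]
#' restores an equal [hurdle_params].
#'
#' @param params a [hurdle_params]
#' @param path output path
#' @return invisibly, the path
#' @export
write_params_json <- function(params, path) {
  obj <- list(
    clusters = lapply(seq_along(params$p), function(k) list(
      p = params$p[k], mu = params$mu[k, ],
      gamma0 = params$gamma0[k, ], gamma1 = params$gamma1[k, ])),
    alpha = params$alpha, s = params$s, variant = params$variant)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cl <- obj$clusters
  hurdle_params(p = vapply(cl, function(x) x$p, numeric(1)),
                mu = do.call(rbind, lapply(cl, function(x) unlist(x$mu))),
                gamma0 = do.call(rbind, lapply(cl, function(x) unlist(x$gamma0))),
                gamma1 = do.call(rbind, lapply(cl, function(x) unlist(x$gamma1))),
                alpha = do.call(rbind, lapply(obj$alpha, unlist)),
                s = unlist(obj$s),
                variant = obj$variant)
}

#' Specification of a simulation experiment grid
#'
#' Describes a one-parameter sweep over the simulator settings: the base
#' configuration, which field varies and over which values, how many
#' replicate datasets per grid point, which fitting methods to run, and
#' whether `K` is fixed (at the true value) or chosen by the hybrid LRT
#' procedure.
#'
#' @param base a [simulation_config]
#' @param vary name of the varied `simulation_config` field (or `NULL` for a
#'   single setting)
#' @param values values the varied field takes
#' @param n_replicates replicate datasets per grid point (>= 1)
#' @param methods subset of `c("em", "sa")`
#' @param k_policy `"fixed"` (fit at the true `K`) or `"choose"` (hybrid
#'   selection)
#' @param n_starts starts per fit
#' @param k_max `k_max` for `k_policy = "choose"`
#' @param seed integer base seed; per-replicate seeds are derived from it
#' @return object of class `experiment_spec`
#' @export
experiment_spec <- function(base = simulation_config(), vary = NULL,
                            values = NULL, n_replicates = 1,
                            methods = c("em", "sa"),
                            k_policy = c("fixed", "choose"),
                            n_starts = 5, k_max = 15, seed = 1) {
  k_policy <- match.arg(k_policy)
  stopifnot(n_replicates >= 1, all(methods %in% c("em", "sa")))
  if (!is.null(vary) && !vary %in% names(unclass(base)))
    stop(sprintf("unknown simulation_config field '%s'", vary))
  if (is.null(vary)) values <- NA
  structure(list(base = base, vary = vary, values = values,
                 n_replicates = n_replicates, methods = methods,
                 k_policy = k_policy, n_starts = n_starts, k_max = k_max,
                 seed = seed),
            class = "experiment_spec")
}

#' Run a simulation experiment
#'
#' For every grid point and replicate: simulate a dataset, fit it with each
#' requested method (at the true `K`, or with hybrid `K` selection), and
#' score the result against the true labels. Per-replicate seeds are derived
#' deterministically from the spec's base seed, so the whole table is
#' reproducible from the spec alone. A replicate whose fit fails is recorded
#' with `NA` scores rather than aborting the run.
#'
#' @param spec an [experiment_spec]
#' @param out_path optional TSV path for the tidy results table
#' @param verbose print one line per replicate
#' @return data frame with columns `setting`, `value`, `replicate`, `method`,
#'   `K_chosen`, `loglik`, `purity`, `ari`, `nmi`, `seed`
#' @export
run_experiment <- function(spec, out_path = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  rows <- list()
  for (si in seq_along(spec$values)) {
    cfg <- spec$base
    if (!is.null(spec$vary)) cfg[[spec$vary]] <- spec$values[si]
    for (ri in seq_len(spec$n_replicates)) {
      rep_seed <- (spec$seed + 99991L * (si - 1L) + 101L * ri) %% 2147483647L
      cfg$seed <- rep_seed
      sim <- simulate_dataset(cfg)
      for (method in spec$methods) {
        row <- tryCatch({
          if (spec$k_policy == "fixed") {
            fit <- multi_start(sim$counts, cfg$K, n_starts = spec$n_starts,
                               method = method, seed = rep_seed)
            kc <- cfg$K
          } else {
            ck <- choose_k(sim$counts, k_max = spec$k_max,
                           n_starts = spec$n_starts, method = method,
                           seed = rep_seed)
            fit <- ck$result
            kc <- ck$K
          }
          data.frame(setting = spec$vary %||% "default",
                     value = spec$values[si], replicate = ri,
                     method = method, K_chosen = kc, loglik = fit$loglik,
                     purity = purity(fit$assignments, sim$labels),
                     ari = adjusted_rand_index(fit$assignments, sim$labels),
                     nmi = nmi(fit$assignments, sim$labels),
                     seed = rep_seed)
        }, error = function(e) {
          warning(sprintf("replicate %d (%s) failed: %s", ri, method,
                          conditionMessage(e)))
          data.frame(setting = spec$vary %||% "default",
                     value = spec$values[si], replicate = ri,
                     method = method, K_chosen = NA_integer_,
                     loglik = NA_real_, purity = NA_real_, ari = NA_real_,
                     nmi = NA_real_, seed = rep_seed)
        })
        rows[[length(rows) + 1]] <- row
        if (verbose)
          message(sprintf("setting %s replicate %d method %s done",
                          rows[[length(rows)]]$setting[1], ri, method))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_path))
    utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
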