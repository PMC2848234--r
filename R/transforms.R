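#' Online data transformations
#'
#' Row-wise transformations of an expression dataset: z-scoring, centering and
#' moving-average smoothing. All transforms keep the matrix shape and the
#' probe/experiment order, ignore missing values, and return a new dataset
#' with an incremented version.
#'
#' `zscore_dataset` scales each row to mean 0 and sample (n-1) standard
#' deviation 1. Constant rows (sd 0) map to all-zero rows rather than
#' erroring, so pipelines applied to filtered data never abort.
#'
#' @param ds an `ExpressionDataSet`.
#' @return a transformed `ExpressionDataSet`.
#' @export
zscore_dataset <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataSet"))
  if (ncol(ds$values) < 2L) {
    stop("z-scoring requires at least 2 experiments", call. = FALSE)
  }
  v <- ds$values
  mu <- rowMeans(v, na.rm = TRUE)
  sdv <- apply(v, 1L, stats::sd, na.rm = TRUE)
  out <- sweep(v, 1L, mu, "-")
  nz <- !is.na(sdv) & sdv > 0
  out[nz, ] <- out[nz, , drop = FALSE] / sdv[nz]
  out[!nz, ] <- ifelse(is.na(v[!nz, , drop = FALSE]), NA_real_, 0)
  bump(ds, values = out)
}

#' @rdname zscore_dataset
#' @param statistic `"mean"` or `"median"`: the row statistic brought to zero.
#' @export
center_dataset <- function(ds, statistic = c("mean", "median")) {
  stopifnot(inherits(ds, "ExpressionDataSet"))
  statistic <- match.arg(statistic)
  v <- ds$values
  ctr <- if (statistic == "mean") rowMeans(v, na.rm = TRUE)
         else apply(v, 1L, stats::median, na.rm = TRUE)
  ctr[is.na(ctr)] <- 0
  bump(ds, values = sweep(v, 1L, ctr, "-"))
}

#' @rdname zscore_dataset
#' @param window odd positive integer: moving-average window width. At the row
#'   edges the window shrinks symmetrically (no padding), so a window of 3
#'   leaves the first and last value untouched except for averaging with the
#'   single available neighbour pair... more precisely, position `i` averages
#'   over `i - h .. i + h` with `h` reduced so both ends stay inside the row.
#' @export
smooth_dataset <- function(ds, window = 3L) {
  stopifnot(inherits(ds, "ExpressionDataSet"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  if (window == 1L) return(bump(ds))
  half <- (window - 1L) %/% 2L
  n <- ncol(ds$values)
  out <- ds$values
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    idx <- (i - h):(i + h)
    out[, i] <- rowMeans(ds$values[, idx, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  bump(ds, values = out)
}

#' Regularized per-probe variance
#'
#' Computes a bounded, rank-preserving variance score per probe,
#' `v' = v / (v + v0)`, where `v` is the sample variance of the probe's row
#' and `v0` the median of all per-probe variances. The score lies in `[0, 1)`
#' and is strictly monotone in the raw variance (for `v0 > 0`), making it a
#' robust basis for "most variant probes" filtering with an absolute
#' threshold. Rows with fewer than two finite values get score 0 with a
#' warning.
#'
#' @param ds an `ExpressionDataSet` with at least two experiments.
#' @return a numeric `MetaInfoGroup` named `"regularized_variance"`.
#' @export
regularized_variance <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataSet"))
  if (ncol(ds$values) < 2L) {
    stop("variance requires at least 2 experiments", call. = FALSE)
  }
  nfin <- rowSums(is.finite(ds$values))
  v <- apply(ds$values, 1L, stats::var, na.rm = TRUE)
  bad <- nfin < 2L
  if (any(bad)) {
    warning(sprintf("%d probe(s) with <2 finite values: variance set to 0",
                    sum(bad)), call. = FALSE)
    v[bad] <- 0
  }
  v0 <- stats::median(v)
  score <- if (v0 > 0) v / (v + v0) else ifelse(v > 0, v / (v + v), 0)
  meta_info_group("regularized_variance", "numeric",
                  stats::setNames(score, probes(ds)))
}

#' Filter probes by a numeric meta-info threshold
#'
#' Keeps probes whose meta value is `>= threshold`; the canonical companion of
#' [regularized_variance()] for building a "most variant probes" list.
#'
#' @param meta a numeric `MetaInfoGroup`.
#' @param threshold numeric cutoff.
#' @param name name for the resulting probe list.
#' @return a `ProbeList`.
#' @export
threshold_filter <- function(meta, threshold, name = NULL) {
  stopifnot(inherits(meta, "MetaInfoGroup"), meta$kind == "numeric")
  if (is.null(name)) name <- sprintf("%s >= %g", meta$name, threshold)
  keep <- names(meta$values)[!is.na(meta$values) & meta$values >= threshold]
  probe_list(name, keep)
}

#' Merge and split expression datasets
#'
#' `merge_datasets` concatenates the experiment columns of two datasets over
#' an identical probe set (A's columns first); experiment names must be
#' disjoint. `split_dataset` partitions a dataset either by a probe list
#' (rows) or by an experiment subset (columns) into the selected part and the
#' remainder; merging the two column parts back restores the original values.
#'
#' @param dsA,dsB `ExpressionDataSet`s with identical probe sets.
#' @return `merge_datasets`: one combined dataset. `split_dataset`: a list
#'   with elements `selected` and `rest`.
#' @export
merge_datasets <- function(dsA, dsB) {
  stopifnot(inherits(dsA, "ExpressionDataSet"), inherits(dsB, "ExpressionDataSet"))
  if (!identical(probes(dsA), probes(dsB))) {
    stop("merge requires identical probe sets (same order)", call. = FALSE)
  }
  if (length(intersect(experiments(dsA), experiments(dsB)))) {
    stop("experiment name collision between datasets", call. = FALSE)
  }
  times <- if (!is.null(dsA$times) && !is.null(dsB$times)) c(dsA$times, dsB$times)
  expression_dataset(cbind(dsA$values, dsB$values),
                     name = paste(dsA$name, dsB$name, sep = "+"), times = times)
}

#' @rdname merge_datasets
#' @param ds dataset to split.
#' @param by a `ProbeList` (row split) or character vector of experiment
#'   names (column split).
#' @export
split_dataset <- function(ds, by) {
  stopifnot(inherits(ds, "ExpressionDataSet"))
  if (inherits(by, "ProbeList")) {
    sel <- by$members
    if (!all(sel %in% probes(ds))) stop("probe list not within dataset", call. = FALSE)
    rest <- setdiff(probes(ds), sel)
    mk <- function(rows, tag) {
      m <- ds$values[rows, , drop = FALSE]
      expression_dataset(m, name = paste0(ds$name, tag), times = ds$times)
    }
    list(selected = mk(sel, ".sel"), rest = mk(rest, ".rest"))
  } else {
    sel <- as.character(by)
    if (!all(sel %in% experiments(ds))) stop("unknown experiment in split", call. = FALSE)
    rest <- setdiff(experiments(ds), sel)
    mk <- function(cols, tag) {
      expression_dataset(ds$values[, cols, drop = FALSE],
                         name = paste0(ds$name, tag),
                         times = if (!is.null(ds$times)) ds$times[cols])
    }
    list(selected = mk(sel, ".sel"), rest = mk(rest, ".rest"))
  }
}
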