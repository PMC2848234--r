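#' Two-group experiment design
#'
#' Assigns every experiment of a dataset to group A or B (e.g. before vs
#' after a metabolic switch). Both groups must be non-empty; the t-test
#' additionally needs at least two experiments per group.
#'
#' @param group_a,group_b character vectors of experiment names.
#' @return an object of class `TwoGroupDesign`.
#' @export
two_group_design <- function(group_a, group_b) {
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) {
    stop("experiment assigned to both groups", call. = FALSE)
  }
  structure(list(A = group_a, B = group_b), class = "TwoGroupDesign")
}

check_design <- function(ds, design) {
  stopifnot(inherits(design, "TwoGroupDesign"))
  miss <- setdiff(c(design$A, design$B), experiments(ds))
  if (length(miss)) stop("unknown experiments: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  design
}

#' Per-probe two-sample t-test
#'
#' Classical two-sided two-sample t-test for every probe, pooled-variance
#' (Student) by default or Welch. Returns the statistic, raw and adjusted
#' p-values and the significance rank per probe.
#'
#' @param ds an `ExpressionDataSet` without missing values in the used
#'   columns.
#' @param design a `TwoGroupDesign` with `>= 2` experiments per group.
#' @param variant `"pooled"` or `"welch"`.
#' @param adjust multiple-testing correction passed to [adjust_p()].
#' @return a `data.frame` (probe, statistic, df, p, adj_p, rank), ranked by
#'   ascending p.
#' @export
t_test_probes <- function(ds, design, variant = c("pooled", "welch"),
                          adjust = "BH") {
  variant <- match.arg(variant)
  check_design(ds, design)
  if (length(design$A) < 2L || length(design$B) < 2L) {
    stop("t-test needs >= 2 experiments per group", call. = FALSE)
  }
  a <- ds$values[, design$A, drop = FALSE]
  b <- ds$values[, design$B, drop = FALSE]
  if (anyNA(a) || anyNA(b)) stop("missing values in tested columns", call. = FALSE)
  res <- t(vapply(seq_len(nrow(a)), function(i) {
    tt <- stats::t.test(b[i, ], a[i, ], var.equal = (variant == "pooled"))
    c(tt$statistic, tt$parameter, tt$p.value)
  }, numeric(3)))
  out <- data.frame(probe = probes(ds), statistic = res[, 1], df = res[, 2],
                    p = res[, 3], stringsAsFactors = FALSE)
  out$adj_p <- adjust_p(out$p, method = adjust)
  out$rank <- rank(out$p, ties.method = "min")
  out[order(out$p), ]
}

#' Weighted average difference (WAD)
#'
#' Ranks probes by the mean group difference weighted by relative average
#' expression: `WAD_i = (mean_B - mean_A) * w_i` with
#' `w_i = (xbar_i - min(xbar)) / (max(xbar) - min(xbar))`, where `xbar_i` is
#' probe i's mean over *all* experiments in the design. On log-scale data
#' this up-weights genes that are both strongly changed and highly
#' expressed. If all probes share the same average expression the weights
#' degenerate to 1. WAD has no p-value by construction; the table reports
#' the statistic and its rank by absolute value.
#'
#' @inheritParams t_test_probes
#' @return a `data.frame` (probe, wad, weight, rank), ranked by `|wad|`
#'   descending.
#' @export
wad_statistic <- function(ds, design) {
  check_design(ds, design)
  a <- ds$values[, design$A, drop = FALSE]
  b <- ds$values[, design$B, drop = FALSE]
  diff <- rowMeans(b) - rowMeans(a)
  xbar <- rowMeans(cbind(a, b))
  rng <- max(xbar) - min(xbar)
  w <- if (rng == 0) rep(1, length(xbar)) else (xbar - min(xbar)) / rng
  wad <- diff * w
  out <- data.frame(probe = probes(ds), wad = wad, weight = w,
                    rank = rank(-abs(wad), ties.method = "min"),
                    stringsAsFactors = FALSE)
  out[order(out$rank), ]
}

#' Rank product with permutation-based PFP
#'
#' Computes, for every probe, the geometric mean of its fold-change ranks
#' over all A-by-B pairwise comparisons (the unpaired scheme: each of the
#' `|A| * |B|` pairs contributes one log fold change, ranked across probes).
#' `direction = "up"` ranks the largest B-minus-A change first, `"down"` the
#' most negative. Significance is estimated by permutation: within each
#' comparison the probe values are shuffled, null rank products are
#' recomputed, and the percentage of false positives for probe i is
#' `PFP(i) = E[number of null RPs <= RP_i] / rank_i`. Fully deterministic
#' given `seed`.
#'
#' @inheritParams t_test_probes
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed integer RNG seed.
#' @param direction `"up"` or `"down"`.
#' @return a `data.frame` (probe, rp, rank, pfp), sorted by ascending RP.
#' @export
rank_product <- function(ds, design, n_perm = 100L, seed = 1L,
                         direction = c("up", "down")) {
  direction <- match.arg(direction)
  check_design(ds, design)
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  a <- ds$values[, design$A, drop = FALSE]
  b <- ds$values[, design$B, drop = FALSE]
  g <- nrow(a)
  pairs <- expand.grid(ia = seq_along(design$A), ib = seq_along(design$B))
  k <- nrow(pairs)
  fc <- matrix(0, g, k)  # per-comparison log fold changes
  for (j in seq_len(k)) {
    fc[, j] <- b[, pairs$ib[j]] - a[, pairs$ia[j]]
  }
  if (direction == "down") fc <- -fc
  rank_mat <- apply(fc, 2L, function(col) rank(-col, ties.method = "average"))
  rp <- exp(rowMeans(log(rank_mat)))
  rp_rank <- rank(rp, ties.method = "min")

  old <- local_seed(seed)
  on.exit(restore_seed(old))
  sorted_rp <- sort(rp)
  exceed <- numeric(g)  # E[# null RP <= RP_i], accumulated over permutations
  for (p in seq_len(n_perm)) {
    null_ranks <- vapply(seq_len(k), function(j) sample.int(g), integer(g))
    null_rp <- exp(rowMeans(log(null_ranks)))
    cnt <- findInterval(sorted_rp, sort(null_rp))
    exceed <- exceed + cnt[match(rp, sorted_rp)]
  }
  e_val <- exceed / n_perm
  pfp <- pmin(e_val / rp_rank, Inf)
  out <- data.frame(probe = probes(ds), rp = rp, rank = rp_rank, pfp = pfp,
                    stringsAsFactors = FALSE)
  out[order(out$rp), ]
}

#' Multiple-testing correction
#'
#' Adjusts raw p-values with Bonferroni, Holm or Benjamini-Hochberg,
#' including the usual monotonicity enforcement and capping at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"`, `"holm"` or `"BH"`.
#' @return adjusted p-values, same order as input.
#' @export
adjust_p <- function(pvals, method = c("BH", "bonferroni", "holm")) {
  method <- match.arg(method)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = method)
}

#' Attach a result column as meta-information
#'
#' Turns one numeric column of a result table (e.g. raw p, PFP or WAD) into
#' a `MetaInfoGroup`, so statistics can feed filter rules such as
#' `rule_meta("p", "<", 0.05)`.
#'
#' @param table result `data.frame` with a `probe` column.
#' @param column column name to extract.
#' @param name meta group name (defaults to the column name).
#' @return a numeric `MetaInfoGroup`.
#' @export
result_to_meta <- function(table, column, name = column) {
  stopifnot(is.data.frame(table), column %in% names(table))
  meta_info_group(name, "numeric",
                  stats::setNames(table[[column]], table$probe))
}
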