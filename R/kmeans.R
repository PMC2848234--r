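#' Seeded k-means clustering (k-means++ initialisation, Lloyd iterations)
#'
#' Partitions the rows of a matrix (or the probes of a dataset) into `k`
#' clusters. Centers are initialised with k-means++ from an explicit seed, so
#' results are fully reproducible; Lloyd iterations run until the assignment
#' reaches a fixpoint or `max_iter` is hit. The within-cluster sum of squares
#' is non-increasing across iterations. Assignment ties go to the
#' smallest-index center.
#'
#' @param x an `ExpressionDataSet` or numeric matrix (items in rows, no
#'   missing values).
#' @param k number of clusters, `1 <= k <=` number of items.
#' @param seed integer seed for the k-means++ draw.
#' @param max_iter maximum number of Lloyd iterations.
#' @return a `Partition`; attribute `"withinss"` holds the final total
#'   within-cluster sum of squares, `"iterations"` the iteration count.
#' @export
kmeans_cluster <- function(x, k, seed = 1L, max_iter = 100L) {
  mat <- if (inherits(x, "ExpressionDataSet")) x$values else x
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) stop("k-means requires complete data", call. = FALSE)
  n <- nrow(mat)
  if (k < 1L || k > n) stop("`k` must be in 1..n", call. = FALSE)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("item", seq_len(n))

  centers <- kmeanspp_init(mat, k, seed)
  lab <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(mat^2), rowSums(centers^2), "+") - 2 * mat %*% t(centers)
    new_lab <- max.col(-d2, ties.method = "first")
    # keep empty clusters alive: give them the point farthest from its center
    for (cl in seq_len(k)) {
      if (!any(new_lab == cl)) {
        far <- which.max(d2[cbind(seq_len(n), new_lab)])
        new_lab[far] <- cl
      }
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
    for (cl in seq_len(k)) {
      centers[cl, ] <- colMeans(mat[lab == cl, , drop = FALSE])
    }
  }
  wss <- sum((mat - centers[lab, , drop = FALSE])^2)
  p <- partition(stats::setNames(lab, rownames(mat)))
  attr(p, "withinss") <- wss
  attr(p, "iterations") <- iter
  p
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center.
kmeanspp_init <- function(mat, k, seed) {
  n <- nrow(mat)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((mat - matrix(mat[idx[1L], ], n, ncol(mat), byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1L, prob = prob)
      nd2 <- rowSums((mat - matrix(mat[idx[j], ], n, ncol(mat), byrow = TRUE))^2)
      d2 <- pmin(d2, nd2)
    }
  }
  mat[idx, , drop = FALSE]
}

# Seed scoping helpers: set the RNG inside a function without clobbering the
# caller's random state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
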