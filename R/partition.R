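#' Flat clustering result
#'
#' A partition maps items to dense 1-based integer cluster labels; items the
#' algorithm could not place (QT clustering leftovers) are carried in a
#' separate `unassigned` vector.
#'
#' @param labels named integer vector (names = item identifiers, values =
#'   cluster labels `1..k` with every label used).
#' @param unassigned character vector of unplaced item names.
#' @return an object of class `Partition`.
#' @export
partition <- function(labels, unassigned = character()) {
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (is.null(names(labels)) && length(labels)) {
    stop("labels must be named by item", call. = FALSE)
  }
  if (length(labels)) {
    u <- sort(unique(labels))
    if (!identical(u, seq_along(u))) {
      # re-densify
      labels[] <- match(labels, u)
    }
  }
  if (length(intersect(names(labels), unassigned))) {
    stop("item both assigned and unassigned", call. = FALSE)
  }
  structure(list(labels = labels, unassigned = as.character(unassigned)),
            class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  k <- if (length(x$labels)) max(x$labels) else 0L
  cat(sprintf("<Partition> %d items in %d clusters, %d unassigned\n",
              length(x$labels), k, length(x$unassigned)))
  invisible(x)
}

#' @rdname partition
#' @param p a `Partition`.
#' @export
n_clusters <- function(p) if (length(p$labels)) max(p$labels) else 0L

#' @rdname partition
#' @export
cluster_members <- function(p) {
  split(names(p$labels), p$labels)
}

#' Compare two partitions with the adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same item set (unassigned items are excluded from both sides and must
#' leave the same assigned set). The index is 1 for identical partitions up
#' to relabeling and has expectation 0 under random labeling.
#'
#' @param p1,p2 `Partition` objects over the same items.
#' @return the adjusted Rand index, a single number `<= 1`.
#' @export
compare_partitions <- function(p1, p2) {
  stopifnot(inherits(p1, "Partition"), inherits(p2, "Partition"))
  i1 <- names(p1$labels); i2 <- names(p2$labels)
  common <- intersect(i1, i2)
  if (!setequal(i1, i2)) {
    stop("partitions cover different item sets", call. = FALSE)
  }
  a <- p1$labels[common]
  b <- p2$labels[common]
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(common)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both trivial partitions
  (sum_ij - expected) / (max_index - expected)
}

#' Silhouette widths for a partition
#'
#' For each assigned item `i`, `a(i)` is its mean distance to the other
#' members of its own cluster and `b(i)` the smallest mean distance to any
#' other cluster; the silhouette width is `s(i) = (b - a) / max(a, b)`.
#' Members of singleton clusters get `s = 0` by convention. Requires at least
#' two non-empty clusters.
#'
#' @param p a `Partition`.
#' @param dm symmetric distance matrix covering all assigned items.
#' @return list with `widths` (named numeric, in `[-1, 1]`) and `mean`.
#' @export
silhouette_widths <- function(p, dm) {
  stopifnot(inherits(p, "Partition"))
  dm <- check_distmatrix(dm)
  items <- names(p$labels)
  if (!all(items %in% rownames(dm))) {
    stop("distance matrix does not cover all assigned items", call. = FALSE)
  }
  k <- n_clusters(p)
  if (k < 2L) stop("silhouette requires at least 2 clusters", call. = FALSE)
  lab <- p$labels
  s <- stats::setNames(numeric(length(items)), items)
  for (i in items) {
    own <- setdiff(items[lab == lab[[i]]], i)
    if (!length(own)) { s[[i]] <- 0; next }  # singleton convention
    a <- mean(dm[i, own])
    b <- min(vapply(setdiff(seq_len(k), lab[[i]]), function(cl) {
      mean(dm[i, items[lab == cl]])
    }, numeric(1)))
    s[[i]] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(widths = s, mean = mean(s))
}
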