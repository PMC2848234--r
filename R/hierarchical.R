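#' Average-linkage hierarchical clustering (UPGMA / WPGMA)
#'
#' Classical agglomerative clustering of a distance matrix. At every step the
#' closest pair of clusters is merged at an ultrametric node height of half
#' their distance; ties are broken by the smallest (row, column) index pair.
#' With `linkage = "upgma"` the distance update weights each cluster by its
#' size (so the new distance is the unweighted average over all item pairs);
#' with `"wpgma"` both clusters contribute equally regardless of size. On an
#' exactly ultrametric input, UPGMA reproduces all pairwise (cophenetic)
#' distances.
#'
#' @param dm square symmetric distance matrix with zero diagonal (row names
#'   become leaf labels).
#' @param linkage `"upgma"` or `"wpgma"`.
#' @return a rooted `phylo` tree (see \pkg{ape}) with branch lengths;
#'   attribute `"merge_pairs"` records the merge sequence as pairs of leaf
#'   label sets, `"merge_heights"` the corresponding node heights.
#' @export
agglomerate <- function(dm, linkage = c("upgma", "wpgma")) {
  linkage <- match.arg(linkage)
  dm <- check_distmatrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 items", call. = FALSE)
  labels <- rownames(dm)

  work <- dm
  active <- seq_len(n)
  frag <- labels                      # newick fragment per active cluster
  height <- rep(0, n)                 # ultrametric height of each cluster
  size <- rep(1L, n)
  members <- as.list(labels)
  merge_pairs <- list()
  merge_heights <- numeric(0)

  while (length(active) > 1L) {
    # smallest distance, tie -> smallest (i, j) index pair in current order
    best_i <- best_j <- NA_integer_; best_d <- Inf
    for (a in seq_along(active)[-length(active)]) {
      for (b in (a + 1L):length(active)) {
        dij <- work[active[a], active[b]]
        if (dij < best_d) { best_d <- dij; best_i <- a; best_j <- b }
      }
    }
    i <- active[best_i]; j <- active[best_j]
    h <- best_d / 2
    merge_pairs[[length(merge_pairs) + 1L]] <- list(members[[i]], members[[j]])
    merge_heights <- c(merge_heights, h)

    frag[i] <- sprintf("(%s:%s,%s:%s)",
                       frag[i], fmt_len(h - height[i]),
                       frag[j], fmt_len(h - height[j]))
    # distance update against every other active cluster
    others <- setdiff(active, c(i, j))
    for (k in others) {
      work[i, k] <- work[k, i] <- if (linkage == "upgma") {
        (size[i] * work[i, k] + size[j] * work[j, k]) / (size[i] + size[j])
      } else {
        (work[i, k] + work[j, k]) / 2
      }
    }
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- size[i] + size[j]
    height[i] <- h
    active <- setdiff(active, j)
  }

  tree <- ape::read.tree(text = paste0(frag[active], ";"))
  attr(tree, "merge_pairs") <- merge_pairs
  attr(tree, "merge_heights") <- merge_heights
  tree
}

# exact-ish decimal formatting for newick branch lengths
fmt_len <- function(x) sprintf("%.15g", max(x, 0))
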