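#' Quality-threshold (QT) clustering
#'
#' Greedy clustering in which the tunable parameter is the desired cluster
#' quality — the *diameter*, i.e. the maximum pairwise distance allowed
#' inside a cluster — instead of the number of clusters. For every unassigned
#' item a candidate cluster is grown by repeatedly adding the item that
#' causes the smallest increase of the candidate's diameter, as long as the
#' diameter stays within the threshold. The largest candidate is accepted,
#' its members are removed, and the procedure repeats until the largest
#' remaining candidate would be smaller than `min_size`; leftover items are
#' reported as unassigned. All ties are broken by smallest item index, so the
#' result is deterministic.
#'
#' @param x an `ExpressionDataSet`, a numeric matrix (items in rows) or a
#'   precomputed symmetric distance matrix (see `is_distance`).
#' @param diameter positive diameter threshold (in units of the chosen
#'   distance; e.g. 0.4 under Pearson correlation distance on z-scored
#'   profiles).
#' @param min_size smallest acceptable cluster size (default 2).
#' @param measure a `DistanceMeasure` used when `x` holds profiles.
#' @param is_distance set `TRUE` if `x` is already a distance matrix.
#' @return a `Partition` with clusters numbered in non-increasing size order;
#'   every cluster's true max pairwise distance is `<= diameter`.
#' @export
qt_cluster <- function(x, diameter, min_size = 2L,
                       measure = distance_measure("euclidean"),
                       is_distance = FALSE) {
  if (!is.numeric(diameter) || diameter <= 0) {
    stop("`diameter` must be positive", call. = FALSE)
  }
  dm <- if (is_distance) check_distmatrix(x) else {
    mat <- if (inherits(x, "ExpressionDataSet")) x$values else x
    distance_matrix(mat, measure)
  }
  items <- rownames(dm)
  n <- length(items)
  active <- rep(TRUE, n)
  clusters <- list()

  grow_candidate <- function(seed, active) {
    member <- seed
    in_cl <- logical(n); in_cl[seed] <- TRUE
    # dmax[x]: max distance from x to current members; candidate diameter
    # after adding x is max(diam, dmax[x])
    dmax <- dm[seed, ]
    diam <- 0
    repeat {
      cand <- which(active & !in_cl)
      if (!length(cand)) break
      best <- cand[which.min(dmax[cand])]  # which.min = smallest index on ties
      newdiam <- max(diam, dmax[best])
      if (newdiam > diameter) break
      in_cl[best] <- TRUE
      member <- c(member, best)
      diam <- newdiam
      dmax <- pmax(dmax, dm[best, ])
    }
    member
  }

  repeat {
    seeds <- which(active)
    if (!length(seeds)) break
    best <- NULL
    for (s in seeds) {
      cand <- grow_candidate(s, active)
      if (is.null(best) || length(cand) > length(best)) best <- cand
    }
    if (length(best) < min_size) break
    clusters[[length(clusters) + 1L]] <- items[best]
    active[best] <- FALSE
  }

  # acceptance order is size order in all but pathological tie cases; make
  # the non-increasing-size contract unconditional
  if (length(clusters) > 1L) {
    clusters <- clusters[order(-lengths(clusters), seq_along(clusters))]
  }
  labels <- integer(0)
  for (cl in seq_along(clusters)) {
    labels <- c(labels, stats::setNames(rep(cl, length(clusters[[cl]])),
                                        clusters[[cl]]))
  }
  partition(labels, unassigned = items[active])
}
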