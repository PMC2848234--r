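#' Neighbor-joining tree construction (naive and rapid variants)
#'
#' Canonical neighbor-joining on a distance matrix: at every step join the
#' pair minimising `Q(i,j) = (n-2) d(i,j) - r_i - r_j` (with `r_i` the sum of
#' row `i` over active clusters), attach the pair at branch lengths given by
#' the standard NJ formulas, and replace it by a new node with reduced
#' distances `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Negative branch
#' lengths are clamped to zero with a warning. Ties in `Q` are broken by the
#' smallest (i, j) index pair.
#'
#' The `"rapid"` variant keeps a sorted candidate list per row and prunes the
#' `Q` search with the upper bound `r_max = max_k r_k`: scanning row `i` in
#' ascending distance order, once
#' `(n-2) d(i,j) - r_i - r_max` can no longer beat the best `Q` seen, the
#' rest of the row is skipped. Because the bound is conservative and
#' tie-breaking is identical, the rapid variant returns the same tree as the
#' naive search.
#'
#' On additive (tree-metric) input the original tree, including branch
#' lengths, is recovered exactly.
#'
#' @param dm square symmetric distance matrix, zero diagonal, `n >= 3`.
#' @param algorithm `"rapid"` (default) or `"naive"`.
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm, algorithm = c("rapid", "naive")) {
  algorithm <- match.arg(algorithm)
  dm <- check_distmatrix(dm)
  n0 <- nrow(dm)
  if (n0 < 3L) stop("neighbor-joining requires n >= 3", call. = FALSE)

  work <- dm
  active <- seq_len(n0)
  frag <- rownames(dm)
  clamped <- FALSE
  # rapid variant: per-row ascending-distance candidate lists. A merge reuses
  # the smaller slot for the new node, whose distances differ from the old
  # occupant's, so each slot carries a creation stamp and lists record when
  # they were built: stale entries (nodes recreated after the list was
  # built) are skipped, and every pair is reachable through the row of its
  # younger member, whose list is fresh.
  sorted_rows <- vector("list", n0)
  created <- integer(n0)
  built <- integer(n0)
  step <- 0L
  rebuild_row <- function(i, active) {
    others <- setdiff(active, i)
    others[order(work[i, others], others)]
  }
  if (algorithm == "rapid") {
    for (i in active) sorted_rows[[i]] <- rebuild_row(i, active)
  }

  while (length(active) > 2L) {
    m <- length(active)
    r <- vapply(active, function(i) sum(work[i, active]), numeric(1))
    names(r) <- as.character(active)
    rsum <- function(i) r[[as.character(i)]]

    best_i <- best_j <- NA_integer_; best_q <- Inf
    if (algorithm == "naive") {
      for (a in seq_len(m - 1L)) {
        for (b in (a + 1L):m) {
          i <- active[a]; j <- active[b]
          q <- (m - 2) * work[i, j] - rsum(i) - rsum(j)
          if (q < best_q) { best_q <- q; best_i <- i; best_j <- j }
        }
      }
    } else {
      r_max <- max(r)
      is_active <- logical(n0); is_active[active] <- TRUE
      for (i in active) {
        ri <- rsum(i)
        for (j in sorted_rows[[i]]) {
          if (!is_active[j] || created[j] > built[i]) next  # retired or stale
          bound <- (m - 2) * work[i, j] - ri - r_max
          if (bound > best_q) break           # nothing better further out
          q <- (m - 2) * work[i, j] - ri - rsum(j)
          lo <- min(i, j); hi <- max(i, j)
          if (q < best_q ||
              (q == best_q && !is.na(best_i) &&
               (lo < best_i || (lo == best_i && hi < best_j)))) {
            best_q <- q; best_i <- lo; best_j <- hi
          }
        }
      }
    }

    i <- min(best_i, best_j); j <- max(best_i, best_j)
    li <- work[i, j] / 2 + (rsum(i) - rsum(j)) / (2 * (m - 2))
    lj <- work[i, j] - li
    if (li < 0 || lj < 0) clamped <- TRUE
    frag[i] <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_len(li), frag[j], fmt_len(lj))
    for (k in setdiff(active, c(i, j))) {
      work[i, k] <- work[k, i] <- (work[i, k] + work[j, k] - work[i, j]) / 2
    }
    active <- setdiff(active, j)
    if (algorithm == "rapid") {
      step <- step + 1L
      created[i] <- step
      sorted_rows[[i]] <- rebuild_row(i, active)
      built[i] <- step
    }
  }

  a <- active[1L]; b <- active[2L]
  # splice the final edge into an internal (parenthesised) fragment so the
  # result is a proper unrooted tree with a degree-3 basal node
  if (!grepl("^\\(", frag[a])) { tmp <- a; a <- b; b <- tmp }
  if (work[a, b] < 0) clamped <- TRUE
  newick <- sub("\\)$", sprintf(",%s:%s)", frag[b], fmt_len(work[a, b])), frag[a])
  if (clamped) {
    warning("negative NJ branch length(s) clamped to 0", call. = FALSE)
  }
  ape::read.tree(text = paste0(newick, ";"))
}
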