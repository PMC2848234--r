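#' Distance measures
#'
#' Distances between expression profiles. Supported kinds: `"euclidean"`,
#' `"manhattan"`, `"minkowski"` (with exponent `p > 0`) and
#' `"pearson"` — the Pearson correlation distance `1 - r`, which lies in
#' `[0, 2]` and requires non-constant vectors. Minkowski with `p = 2` equals
#' euclidean, `p = 1` equals manhattan.
#'
#' @param kind distance kind.
#' @param p Minkowski exponent (ignored for other kinds).
#' @return an object of class `DistanceMeasure`.
#' @examples
#' profile_distance(c(0, 0), c(3, 4), distance_measure("euclidean"))  # 5
#' @export
distance_measure <- function(kind = c("euclidean", "manhattan", "minkowski",
                                      "pearson"), p = 2) {
  kind <- match.arg(kind)
  if (kind == "minkowski" && (!is.numeric(p) || p <= 0)) {
    stop("minkowski exponent `p` must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, p = p), class = "DistanceMeasure")
}

#' @rdname distance_measure
#' @param x,y numeric vectors of equal length.
#' @param m a `DistanceMeasure`.
#' @export
profile_distance <- function(x, y, m = distance_measure("euclidean")) {
  stopifnot(inherits(m, "DistanceMeasure"))
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  switch(m$kind,
    euclidean = sqrt(sum((x - y)^2)),
    manhattan = sum(abs(x - y)),
    minkowski = sum(abs(x - y)^m$p)^(1 / m$p),
    pearson = {
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        stop("pearson distance undefined for constant vectors", call. = FALSE)
      }
      1 - stats::cor(x, y)
    }
  )
}

#' All pairwise distances between rows of a matrix
#'
#' @param mat numeric matrix (items in rows).
#' @param m a `DistanceMeasure`.
#' @return symmetric matrix with zero diagonal, dimnames from `mat` rows.
#' @export
distance_matrix <- function(mat, m = distance_measure("euclidean")) {
  stopifnot(inherits(m, "DistanceMeasure"))
  d <- switch(m$kind,
    euclidean = stats::dist(mat, method = "euclidean"),
    manhattan = stats::dist(mat, method = "manhattan"),
    minkowski = stats::dist(mat, method = "minkowski", p = m$p),
    pearson = {
      if (any(apply(mat, 1L, stats::sd) == 0)) {
        stop("pearson distance undefined for constant rows", call. = FALSE)
      }
      stats::as.dist(1 - stats::cor(t(mat)))
    }
  )
  dm <- as.matrix(d)
  diag(dm) <- 0
  dimnames(dm) <- list(rownames(mat), rownames(mat))
  dm
}

# Validate a distance matrix argument: square, symmetric, zero diagonal.
check_distmatrix <- function(dm, tol = 1e-8) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (max(abs(dm - t(dm))) > tol) stop("distance matrix not symmetric", call. = FALSE)
  if (max(abs(diag(dm))) > tol) stop("distance matrix diagonal not zero", call. = FALSE)
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("item", seq_len(nrow(dm)))
  }
  dm
}
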