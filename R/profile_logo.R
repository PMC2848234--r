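#' Expression bin definitions for profile logos
#'
#' A profile logo discretises expression into `B` bins delimited by `B - 1`
#' strictly ascending thresholds, e.g. `c(-1, 1)` for down-regulated /
#' unchanged / up-regulated on z-scored data. The bin convention is
#' left-open, right-closed: `(-Inf, t1], (t1, t2], ..., (t_{B-1}, Inf)`.
#'
#' @param thresholds strictly increasing numeric vector (length `B - 1`).
#' @param labels optional bin labels, low to high (length `B`).
#' @return an object of class `BinDefinition`.
#' @export
bin_definition <- function(thresholds, labels = NULL) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing (>= 1 value)", call. = FALSE)
  }
  nb <- length(thresholds) + 1L
  if (is.null(labels)) {
    labels <- paste0("bin", seq_len(nb))
  } else if (length(labels) != nb) {
    stop("need one label per bin", call. = FALSE)
  }
  structure(list(thresholds = thresholds, labels = labels),
            class = "BinDefinition")
}

#' Compute a profile logo
#'
#' Generalises sequence logos to expression data: for every experiment, the
#' member probes of a probe list are counted into the expression bins, and
#' the counts are scaled to frequencies so each experiment column sums to 1.
#' Frequencies (not counts) make logos of different-sized probe lists
#' directly comparable.
#'
#' @param ds an `ExpressionDataSet`.
#' @param pl a non-empty `ProbeList` (no missing values among its members).
#' @param bins a `BinDefinition`.
#' @return a `LogoMatrix`: numeric matrix bins x experiments (bin order low
#'   to high), every column summing to 1.
#' @export
compute_logo <- function(ds, pl, bins) {
  stopifnot(inherits(ds, "ExpressionDataSet"), inherits(bins, "BinDefinition"))
  members <- if (inherits(pl, "ProbeList") || inherits(pl, "DynamicProbeList")) {
    pl$members
  } else as.character(pl)
  if (!length(members)) stop("empty probe list", call. = FALSE)
  if (!all(members %in% probes(ds))) stop("probe list not within dataset", call. = FALSE)
  v <- ds$values[members, , drop = FALSE]
  if (anyNA(v)) stop("missing values among probe list members", call. = FALSE)
  breaks <- c(-Inf, bins$thresholds, Inf)
  nb <- length(bins$labels)
  out <- vapply(seq_len(ncol(v)), function(j) {
    cnt <- tabulate(cut(v[, j], breaks = breaks, right = TRUE,  # (lo, hi]
                        labels = FALSE), nbins = nb)
    cnt / length(members)
  }, numeric(nb))
  dimnames(out) <- list(bins$labels, experiments(ds))
  structure(out, class = c("LogoMatrix", class(out)))
}

#' Render a profile logo as SVG
#'
#' Writes a static stacked-bar logo: one column per experiment, rectangle
#' heights proportional to bin frequency, bins colour-coded low (blue) to
#' high (red). Zero-frequency bins are omitted.
#'
#' @param logo a `LogoMatrix` from [compute_logo()].
#' @param path output file path.
#' @param width,height canvas size in pixels.
#' @return the path, invisibly.
#' @export
render_logo <- function(logo, path, width = 20L * ncol(logo), height = 200L) {
  stopifnot(inherits(logo, "LogoMatrix"))
  nb <- nrow(logo); ne <- ncol(logo)
  pal <- grDevices::colorRampPalette(c("#2166ac", "#cccccc", "#b2182b"))(nb)
  colw <- width / ne
  rects <- character(0)
  for (j in seq_len(ne)) {
    y <- height
    for (b in seq_len(nb)) {
      h <- logo[b, j] * height
      if (h <= 0) next
      y <- y - h
      rects <- c(rects, sprintf(
        '<rect x="%.4f" y="%.4f" width="%.4f" height="%.4f" fill="%s"><title>%s@%s: %.3f</title></rect>',
        (j - 1) * colw, y, colw * 0.92, h, pal[b],
        rownames(logo)[b], colnames(logo)[j], logo[b, j]))
    }
  }
  svg <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            as.integer(width), as.integer(height), as.integer(width), as.integer(height)),
    rects, "</svg>")
  writeLines(svg, path)
  invisible(path)
}

#' Write a logo matrix as TSV
#' @param logo a `LogoMatrix`.
#' @param path output path.
#' @export
write_logo_tsv <- function(logo, path) {
  write_named_matrix(unclass(logo), path, corner = "bin")
  invisible(path)
}
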