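#' Expression dataset
#'
#' The central container: a real-valued matrix of probes (rows) by
#' experiments (columns), log-scale by convention, with optional per-experiment
#' time annotations (hours) and a monotonically increasing version counter.
#' Every mutating operation returns a new dataset whose version is strictly
#' larger than the input's; read-only operations never touch the version.
#' Dynamic probe lists use the version stamp to decide whether their cached
#' membership is still valid.
#'
#' @param values numeric matrix with unique, non-empty rownames (probes) and
#'   colnames (experiments). Missing values (`NA`) are allowed.
#' @param name dataset name.
#' @param times optional numeric vector of sampling times in hours, one per
#'   experiment (may be named by experiment).
#' @return an object of class `ExpressionDataSet`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("p", 1:3), paste0("e", 1:4)))
#' ds <- expression_dataset(m, name = "demo", times = c(20, 21, 22, 23))
#' dim(ds)
#' @export
expression_dataset <- function(values, name = "dataset", times = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  pn <- rownames(values)
  en <- colnames(values)
  if (is.null(pn) && nrow(values) == 0L) {
    rownames(values) <- pn <- character()
  }
  if (is.null(en) && ncol(values) == 0L) {
    colnames(values) <- en <- character()
  }
  if (is.null(pn) || is.null(en)) {
    stop("`values` must have probe rownames and experiment colnames",
         call. = FALSE)
  }
  if (anyDuplicated(pn)) stop("duplicate probe names", call. = FALSE)
  if (anyDuplicated(en)) stop("duplicate experiment names", call. = FALSE)
  if (any(!nzchar(pn)) || any(!nzchar(en))) {
    stop("empty probe or experiment name", call. = FALSE)
  }
  if (!is.null(times)) {
    if (length(times) != ncol(values)) {
      stop("`times` must have one entry per experiment", call. = FALSE)
    }
    times <- as.numeric(times)
    names(times) <- en
  }
  structure(
    list(name = name, values = values, times = times, version = 1L),
    class = "ExpressionDataSet"
  )
}

#' @export
print.ExpressionDataSet <- function(x, ...) {
  cat(sprintf("<ExpressionDataSet '%s'> %d probes x %d experiments (version %d)\n",
              x$name, nrow(x$values), ncol(x$values), x$version))
  if (!is.null(x$times)) {
    cat(sprintf("  times: %s ... %s h\n", min(x$times), max(x$times)))
  }
  invisible(x)
}

#' @export
dim.ExpressionDataSet <- function(x) dim(x$values)

#' Probe and experiment accessors
#' @param ds an `ExpressionDataSet`.
#' @return character vector of probe (row) or experiment (column) names.
#' @export
probes <- function(ds) rownames(ds$values)

#' @rdname probes
#' @export
experiments <- function(ds) colnames(ds$values)

#' @rdname probes
#' @export
dataset_values <- function(ds) ds$values

#' @rdname probes
#' @export
dataset_version <- function(ds) ds$version

# Internal: derive a dataset from `ds` with new values, bumping the version.
bump <- function(ds, values = ds$values, name = ds$name, times = ds$times) {
  ds$values <- values
  ds$name <- name
  ds$times <- times
  ds$version <- ds$version + 1L
  ds
}

#' Overwrite the expression values of selected probes
#'
#' Returns a new dataset with the given probe rows replaced and the version
#' counter incremented, so that dynamic probe lists know to re-evaluate.
#'
#' @param ds an `ExpressionDataSet`.
#' @param probe probe identifier(s).
#' @param values replacement values, a vector (one probe) or matrix.
#' @return the updated `ExpressionDataSet`.
#' @export
set_probe_values <- function(ds, probe, values) {
  stopifnot(inherits(ds, "ExpressionDataSet"))
  if (!all(probe %in% probes(ds))) stop("unknown probe", call. = FALSE)
  v <- ds$values
  v[probe, ] <- values
  bump(ds, values = v)
}

#' Transpose a dataset (experiment-space analysis)
#'
#' Experiment clustering (e.g. building a tree over time points) is done by
#' clustering the transposed matrix: experiments become rows.
#'
#' @param ds an `ExpressionDataSet`.
#' @return a new `ExpressionDataSet` with probes and experiments swapped.
#' @export
transpose_dataset <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataSet"))
  expression_dataset(t(ds$values), name = paste0(ds$name, ".t"))
}

#' Probe list
#'
#' A named, ordered subset of a dataset's probes; the basic unit of analysis
#' and visualization. Members must be unique.
#'
#' @param name list name.
#' @param members character vector of probe identifiers.
#' @param color optional display tag (e.g. a hex color).
#' @return an object of class `ProbeList`.
#' @export
probe_list <- function(name, members, color = NULL) {
  members <- as.character(members)
  if (anyDuplicated(members)) stop("duplicate probe list members", call. = FALSE)
  structure(list(name = name, members = members, color = color),
            class = "ProbeList")
}

#' @export
print.ProbeList <- function(x, ...) {
  cat(sprintf("<ProbeList '%s'> %d probes\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.ProbeList <- function(x) length(x$members)

#' Typed per-probe meta-information
#'
#' A meta-information group attaches one typed value (numeric, string or
#' category) to some or all probes of a dataset. Partial coverage is allowed;
#' filter rules treat probes without a value as failing the comparison.
#'
#' @param name group name.
#' @param kind one of `"numeric"`, `"string"`, `"category"`.
#' @param values named vector, names are probe identifiers.
#' @return an object of class `MetaInfoGroup`.
#' @export
meta_info_group <- function(name, kind = c("numeric", "string", "category"),
                            values) {
  kind <- match.arg(kind)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("meta values must be named by probe", call. = FALSE)
  }
  if (anyDuplicated(names(values))) stop("duplicate probe keys", call. = FALSE)
  nm <- names(values)
  values <- if (kind == "numeric") {
    v <- suppressWarnings(as.numeric(values))
    if (anyNA(v) && !anyNA(suppressWarnings(as.character(values)))) {
      stop("values do not conform to kind 'numeric'", call. = FALSE)
    }
    v
  } else as.character(values)
  names(values) <- nm
  structure(list(name = name, kind = kind, values = values),
            class = "MetaInfoGroup")
}

#' @export
print.MetaInfoGroup <- function(x, ...) {
  cat(sprintf("<MetaInfoGroup '%s'> kind=%s, %d probes\n",
              x$name, x$kind, length(x$values)))
  invisible(x)
}

#' Genomic annotation records
#'
#' Per-probe genomic loci: replicon (chromosome or plasmid), 1-based inclusive
#' start/end coordinates and strand orientation. Used to derive meta-info
#' groups for filtering (e.g. keep plus-strand probes).
#'
#' @param probe,replicon character vectors.
#' @param start,end integer base-pair coordinates, `1 <= start <= end`.
#' @param strand `"+"` or `"-"` (ASCII minus accepted).
#' @return a `data.frame` of class `AnnotationRecord`.
#' @export
annotation_records <- function(probe, replicon, start, end, strand) {
  strand <- gsub("−", "-", as.character(strand))  # unicode minus
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) stop("non-integer coordinates", call. = FALSE)
  if (any(start < 1L)) stop("start coordinates must be >= 1", call. = FALSE)
  if (any(start > end)) stop("start > end", call. = FALSE)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  structure(
    data.frame(probe = as.character(probe), replicon = as.character(replicon),
               start = start, end = end, strand = strand,
               stringsAsFactors = FALSE),
    class = c("AnnotationRecord", "data.frame")
  )
}

#' Convert annotation records to meta-info groups
#'
#' Produces four groups: numeric `start` and `end`, category `strand` and
#' category `replicon`, suitable for use in filter rules.
#'
#' @param ann an `AnnotationRecord` data frame.
#' @return named list of `MetaInfoGroup` objects.
#' @export
annotation_to_meta <- function(ann) {
  stopifnot(inherits(ann, "AnnotationRecord"))
  nm <- ann$probe
  list(
    start = meta_info_group("start", "numeric", stats::setNames(ann$start, nm)),
    end = meta_info_group("end", "numeric", stats::setNames(ann$end, nm)),
    strand = meta_info_group("strand", "category", stats::setNames(ann$strand, nm)),
    replicon = meta_info_group("replicon", "category", stats::setNames(ann$replicon, nm))
  )
}
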