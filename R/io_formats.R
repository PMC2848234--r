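#' Read and write expression matrices as TSV
#'
#' The matrix format is tab-delimited text: the first row holds experiment
#' names (first cell is a corner label), subsequent rows start with the probe
#' name. Empty cells become missing values. Parsing is strict — ragged rows,
#' duplicate probe or experiment names and non-numeric cells raise an error
#' naming the offending line. Numbers are written with full (round-trip
#' exact) decimal precision and '.' as decimal separator; writers are
#' deterministic.
#'
#' @param path file path.
#' @param name dataset name (defaults to the file's base name).
#' @param times optional numeric times per experiment.
#' @return `read_matrix`: an `ExpressionDataSet`.
#' @export
read_matrix <- function(path, name = NULL, times = NULL) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  if (!length(lines)) stop("empty matrix file", call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  en <- header[-1L]
  if (anyDuplicated(en)) stop("duplicate experiment names in header", call. = FALSE)
  ncol_exp <- length(header)
  pn <- character(length(cells) - 1L)
  vals <- matrix(NA_real_, length(cells) - 1L, length(en))
  for (i in seq_along(cells)[-1L]) {
    row <- cells[[i]]
    if (length(row) != ncol_exp) {
      stop(sprintf("line %d: expected %d fields, got %d", i, ncol_exp,
                   length(row)), call. = FALSE)
    }
    pn[i - 1L] <- row[1L]
    x <- row[-1L]
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(num) & nzchar(x) & !x %in% c("NA", "NaN"))
    if (length(bad)) {
      stop(sprintf("line %d: non-numeric cell '%s'", i, x[bad[1L]]),
           call. = FALSE)
    }
    vals[i - 1L, ] <- num
  }
  dup <- which(duplicated(pn))
  if (length(dup)) {
    stop(sprintf("line %d: duplicate probe name '%s'", dup[1L] + 1L,
                 pn[dup[1L]]), call. = FALSE)
  }
  dimnames(vals) <- list(pn, en)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  expression_dataset(vals, name = name, times = times)
}

#' @rdname read_matrix
#' @param ds an `ExpressionDataSet` to write.
#' @export
write_matrix <- function(ds, path) {
  stopifnot(inherits(ds, "ExpressionDataSet"))
  write_named_matrix(ds$values, path, corner = "probe")
  invisible(path)
}

# deterministic TSV writer for a named numeric matrix
write_named_matrix <- function(m, path, corner = "") {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  header <- paste(c(corner, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read genomic annotations from TSV
#'
#' Expects five tab-separated columns per line: probe, replicon, start, end,
#' strand (1-based inclusive coordinates; strand `+` or `-`, unicode minus
#' accepted). An optional header line starting with `probe` is skipped.
#' Invalid records (start > end, bad strand, non-integer coordinates) raise
#' an error naming the line. An empty file yields zero records.
#'
#' @param path file path.
#' @return an `AnnotationRecord` data frame.
#' @export
read_annotation <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1L], "probe\t")) lines <- lines[-1L]
  if (!length(lines)) {
    return(annotation_records(character(), character(), integer(), integer(),
                              character()))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) != 5L) {
      stop(sprintf("line %d: expected 5 tab-separated fields", i), call. = FALSE)
    }
  }
  m <- do.call(rbind, cells)
  tryCatch(
    annotation_records(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5]),
    error = function(e) {
      # find the offending line for the error message
      for (i in seq_len(nrow(m))) {
        ok <- tryCatch({
          annotation_records(m[i, 1], m[i, 2], m[i, 3], m[i, 4], m[i, 5]); TRUE
        }, error = function(e2) FALSE)
        if (!ok) stop(sprintf("line %d: %s", i, conditionMessage(e)),
                      call. = FALSE)
      }
      stop(conditionMessage(e), call. = FALSE)
    }
  )
}

#' @rdname read_annotation
#' @param ann an `AnnotationRecord` data frame.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "AnnotationRecord"))
  header <- "probe\treplicon\tstart\tend\tstrand"
  body <- sprintf("%s\t%s\t%d\t%d\t%s", ann$probe, ann$replicon, ann$start,
                  ann$end, ann$strand)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Newick serialisation of cluster trees
#'
#' Thin wrappers around the \pkg{ape} Newick reader/writer, the standard
#' interchange format for the trees produced by hierarchical clustering.
#' Round-trips preserve topology and branch lengths to within 1e-9.
#'
#' @param tree a `phylo` object.
#' @param path optional file path; if `NULL`, the Newick string is returned.
#' @return `write_newick`: the Newick string (invisibly if written to file);
#'   `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @param text Newick text (used when `path` is `NULL`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) stop("unbalanced parentheses in Newick", call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop("Newick parse error", call. = FALSE)
  tree
}
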