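#' Analysis snapshots
#'
#' A snapshot saves the complete state of an analysis — the dataset, static
#' and dynamic probe lists (the latter with their rule trees), meta-info
#' groups and cluster trees — into a single compressed container designed
#' for fast storage and retrieval. The container is a gzip-compressed tar of
#' plain-text entries (matrix TSV, probe lists + rules JSON, one TSV per
#' meta group, Newick trees, JSON manifest), so its contents stay
#' human-inspectable; numbers are serialised with round-trip-exact decimal
#' text, giving full fidelity on load. Dynamic probe lists re-evaluate to
#' the same members after loading.
#'
#' @param state a list with elements `dataset` (required), `probelists`
#'   (named list of `ProbeList` / `DynamicProbeList`), `meta` (named list of
#'   `MetaInfoGroup`), `trees` (named list of `phylo`).
#' @param path output file path (conventionally `.snapshot.tar.gz`).
#' @param timestamp creation time recorded in the manifest; pass a fixed
#'   string for reproducible output.
#' @return `save_snapshot`: the path, invisibly. `load_snapshot`: a state
#'   list of the same shape plus `manifest`.
#' @export
save_snapshot <- function(state, path, timestamp = NULL) {
  stopifnot(inherits(state$dataset, "ExpressionDataSet"))
  dir <- tempfile("snapshot")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)

  write_matrix(state$dataset, file.path(dir, "matrix.tsv"))
  pls <- lapply(state$probelists %||% list(), function(pl) {
    if (inherits(pl, "DynamicProbeList")) {
      list(type = "dynamic", name = pl$name, rule = rule_to_list(pl$rule))
    } else {
      list(type = "static", name = pl$name, members = as.list(pl$members),
           color = pl$color)
    }
  })
  manifest <- list(
    format = "exprdeck-snapshot", format_version = "1.0",
    tool_version = as.character(utils::packageVersion("exprdeck")),
    created = timestamp %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    dataset = list(name = state$dataset$name,
                   n_probes = nrow(state$dataset$values),
                   n_experiments = ncol(state$dataset$values),
                   version = state$dataset$version,
                   times = as.list(state$dataset$times)),
    meta_groups = lapply(state$meta %||% list(), function(mg) {
      list(name = mg$name, kind = mg$kind)
    }),
    trees = as.list(names(state$trees %||% list()))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(pls, file.path(dir, "probelists.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(state$meta %||% list())) {
    dir.create(file.path(dir, "meta"))
    for (mg in state$meta) {
      lines <- c("probe\tvalue", sprintf("%s\t%s", names(mg$values),
        if (mg$kind == "numeric") sprintf("%.17g", mg$values) else mg$values))
      writeLines(lines, file.path(dir, "meta", paste0(mg$name, ".tsv")))
    }
  }
  if (length(state$trees %||% list())) {
    dir.create(file.path(dir, "trees"))
    for (nm in names(state$trees)) {
      write_newick(state$trees[[nm]], file.path(dir, "trees", paste0(nm, ".nwk")))
    }
  }

  path <- normalizePath(path, mustWork = FALSE)
  old <- getwd(); on.exit(setwd(old), add = TRUE)
  setwd(dir)
  files <- sort(list.files(".", recursive = TRUE))
  utils::tar(path, files = files, compression = "gzip", tar = "internal")
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  if (!file.exists(path)) stop("snapshot not found: ", path, call. = FALSE)
  dir <- tempfile("unsnap")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  ok <- tryCatch({ utils::untar(path, exdir = dir, tar = "internal"); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  mf_path <- file.path(dir, "manifest.json")
  if (!ok || !file.exists(mf_path)) {
    stop("not a valid snapshot (missing or unreadable manifest)", call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(mf_path, simplifyVector = FALSE)
  if (!identical(manifest$format, "exprdeck-snapshot")) {
    stop("unknown snapshot format", call. = FALSE)
  }
  major <- as.integer(strsplit(manifest$format_version %||% "0", ".",
                               fixed = TRUE)[[1L]][1L])
  if (is.na(major) || major > 1L) {
    stop("unsupported snapshot format version: ", manifest$format_version,
         call. = FALSE)
  }
  ds <- read_matrix(file.path(dir, "matrix.tsv"),
                    name = manifest$dataset$name,
                    times = if (length(manifest$dataset$times)) {
                      unlist(manifest$dataset$times)
                    })
  ds$version <- as.integer(manifest$dataset$version %||% 1L)
  raw_pls <- jsonlite::fromJSON(file.path(dir, "probelists.json"),
                                simplifyVector = FALSE)
  probelists <- lapply(raw_pls, function(p) {
    if (identical(p$type, "dynamic")) {
      dynamic_probe_list(p$name, rule_from_list(p$rule))
    } else {
      probe_list(p$name, unlist(p$members) %||% character(), color = p$color)
    }
  })
  names(probelists) <- vapply(probelists, `[[`, character(1), "name")
  meta <- list()
  for (mg in manifest$meta_groups) {
    f <- file.path(dir, "meta", paste0(mg$name, ".tsv"))
    tab <- utils::read.delim(f, colClasses = "character")
    meta[[mg$name]] <- meta_info_group(mg$name, mg$kind,
                                       stats::setNames(tab$value, tab$probe))
  }
  trees <- list()
  for (nm in unlist(manifest$trees)) {
    trees[[nm]] <- read_newick(file.path(dir, "trees", paste0(nm, ".nwk")))
  }
  list(dataset = ds, probelists = probelists, meta = meta, trees = trees,
       manifest = manifest)
}
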