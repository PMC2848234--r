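#' Operation registry for processing pipelines
#'
#' Pipelines chain registered operations; every operation declares its
#' parameter schema (name -> type) so pipelines can be validated before any
#' execution. The built-in registry covers the common first-level analysis
#' steps: transforms, regularized variance + threshold filtering, rule
#' filtering, transposition, clustering, tree building, profile logos and
#' the differential-expression statistics. Stochastic operations (k-means,
#' rank product) take their seed as an explicit parameter, so pipelines are
#' reproducible by construction.
#'
#' @return named list describing the registered operations.
#' @export
pipeline_operations <- function() {
  lapply(op_registry(), function(op) op$schema)
}

op_registry <- function() {
  reg <- list(
    zscore = list(schema = list(), fun = function(ds, ctx, p) zscore_dataset(ds)),
    center = list(schema = list(statistic = "character"),
                  fun = function(ds, ctx, p) center_dataset(ds, p$statistic %||% "mean")),
    smooth = list(schema = list(window = "integer"),
                  fun = function(ds, ctx, p) smooth_dataset(ds, p$window %||% 3L)),
    regularized_variance = list(schema = list(),
                  fun = function(ds, ctx, p) regularized_variance(ds)),
    threshold_filter = list(schema = list(meta = "slot", threshold = "numeric"),
                  fun = function(ds, ctx, p) threshold_filter(ctx[[p$meta]], p$threshold)),
    filter_rule = list(schema = list(rule = "rule"),
                  fun = function(ds, ctx, p) {
                    rule <- if (inherits(p$rule, "FilterRule")) p$rule
                            else rule_from_list(p$rule)
                    evaluate_rule(rule, ds, context = list(
                      probelists = Filter(function(x) inherits(x, "ProbeList") ||
                                            inherits(x, "DynamicProbeList"), ctx),
                      meta = Filter(function(x) inherits(x, "MetaInfoGroup"), ctx)))
                  }),
    subset_probes = list(schema = list(probelist = "slot"),
                  fun = function(ds, ctx, p) split_dataset(ds, ctx[[p$probelist]])$selected),
    transpose = list(schema = list(),
                  fun = function(ds, ctx, p) transpose_dataset(ds)),
    qt_cluster = list(schema = list(diameter = "numeric", min_size = "integer",
                                    distance = "character"),
                  fun = function(ds, ctx, p) qt_cluster(ds, p$diameter,
                      min_size = p$min_size %||% 2L,
                      measure = distance_measure(p$distance %||% "euclidean",
                                                 p = p$p %||% 2))),
    kmeans = list(schema = list(k = "integer", seed = "integer"),
                  fun = function(ds, ctx, p) kmeans_cluster(ds, p$k, seed = p$seed)),
    neighbor_joining = list(schema = list(distance = "character",
                                          algorithm = "character"),
                  fun = function(ds, ctx, p) neighbor_joining(
                      distance_matrix(ds$values,
                                      distance_measure(p$distance %||% "euclidean")),
                      algorithm = p$algorithm %||% "rapid")),
    agglomerate = list(schema = list(distance = "character", linkage = "character"),
                  fun = function(ds, ctx, p) agglomerate(
                      distance_matrix(ds$values,
                                      distance_measure(p$distance %||% "euclidean")),
                      linkage = p$linkage %||% "upgma")),
    profile_logo = list(schema = list(probelist = "slot", thresholds = "numeric"),
                  fun = function(ds, ctx, p) compute_logo(ds, ctx[[p$probelist]],
                      bin_definition(unlist(p$thresholds)))),
    t_test = list(schema = list(group_a = "character", group_b = "character",
                                variant = "character"),
                  fun = function(ds, ctx, p) t_test_probes(ds,
                      two_group_design(unlist(p$group_a), unlist(p$group_b)),
                      variant = p$variant %||% "pooled")),
    wad = list(schema = list(group_a = "character", group_b = "character"),
                  fun = function(ds, ctx, p) wad_statistic(ds,
                      two_group_design(unlist(p$group_a), unlist(p$group_b)))),
    rank_product = list(schema = list(group_a = "character", group_b = "character",
                                      n_perm = "integer", seed = "integer"),
                  fun = function(ds, ctx, p) rank_product(ds,
                      two_group_design(unlist(p$group_a), unlist(p$group_b)),
                      n_perm = p$n_perm %||% 100L, seed = p$seed %||% 1L))
  )
  reg
}

#' Build a processing pipeline
#'
#' A pipeline is an ordered list of steps. Each step names a registered
#' operation, a parameter record, the slot its primary input is read from
#' (default: the slot the previous step wrote, starting at `"dataset"`) and
#' the slot its output is stored under. Slot references in parameters (type
#' `"slot"`) point at outputs of earlier steps, so the dataflow is acyclic
#' by construction; validation checks operation names, parameter types and
#' slot availability before anything runs.
#'
#' @param name pipeline name.
#' @param steps list of steps, each a list with `op`, optional `params`,
#'   optional `input`, optional `output`.
#' @return an object of class `Pipeline`.
#' @export
pipeline <- function(name, steps) {
  p <- structure(list(name = name, format_version = "1.0", steps = steps),
                 class = "Pipeline")
  validate_pipeline(p)
  p
}

validate_pipeline <- function(p) {
  reg <- op_registry()
  available <- "dataset"
  current <- "dataset"
  for (k in seq_along(p$steps)) {
    st <- p$steps[[k]]
    if (is.null(st$op) || !st$op %in% names(reg)) {
      stop(sprintf("step %d: unknown operation '%s'", k, st$op %||% "<missing>"),
           call. = FALSE)
    }
    schema <- reg[[st$op]]$schema
    for (pn in names(st$params %||% list())) {
      if (!pn %in% c(names(schema), "p")) {
        stop(sprintf("step %d (%s): unknown parameter '%s'", k, st$op, pn),
             call. = FALSE)
      }
      if (identical(schema[[pn]], "slot") &&
          !st$params[[pn]] %in% available) {
        stop(sprintf("step %d (%s): slot '%s' not available", k, st$op,
                     st$params[[pn]]), call. = FALSE)
      }
    }
    input <- st$input %||% current
    if (!input %in% available) {
      stop(sprintf("step %d (%s): input slot '%s' not available", k, st$op,
                   input), call. = FALSE)
    }
    out <- st$output %||% paste0("step", k)
    available <- union(available, out)
    current <- out
  }
  invisible(TRUE)
}

#' Run a pipeline on a dataset
#'
#' Executes the steps in order against a fresh slot environment seeded with
#' the input dataset under slot `"dataset"`. Each step reads its input slot,
#' runs its operation and stores the result under its output slot; the
#' provenance log records, per step, the operation, parameters, input and
#' output slots, the element count of the output and the wall time. A
#' failure at step `k` aborts with an error naming the step; the input
#' dataset is never modified (all outputs are new objects).
#'
#' @param p a `Pipeline`.
#' @param ds an `ExpressionDataSet`.
#' @return list with `slots` (all step outputs by name, including
#'   `dataset`) and `log` (provenance `data.frame`).
#' @export
run_pipeline <- function(p, ds) {
  stopifnot(inherits(p, "Pipeline"), inherits(ds, "ExpressionDataSet"))
  validate_pipeline(p)
  reg <- op_registry()
  slots <- list(dataset = ds)
  current <- "dataset"
  log <- list()
  for (k in seq_along(p$steps)) {
    st <- p$steps[[k]]
    input <- st$input %||% current
    out <- st$output %||% paste0("step", k)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      reg[[st$op]]$fun(slots[[input]], slots, st$params %||% list()),
      error = function(e) {
        stop(sprintf("pipeline '%s' failed at step %d (%s): %s", p$name, k,
                     st$op, conditionMessage(e)), call. = FALSE)
      })
    slots[[out]] <- res
    log[[k]] <- data.frame(
      step = k, op = st$op,
      params = paste(names(st$params %||% list()), collapse = ","),
      input = input, output = out,
      n_elements = element_count(res),
      seconds = round(proc.time()[["elapsed"]] - t0, 4)
    )
    current <- out
  }
  list(slots = slots,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(step = integer(), op = character(), params = character(),
                    input = character(), output = character(),
                    n_elements = integer(), seconds = numeric()))
}

element_count <- function(x) {
  if (inherits(x, "ExpressionDataSet")) nrow(x$values)
  else if (inherits(x, "ProbeList")) length(x$members)
  else if (inherits(x, "MetaInfoGroup")) length(x$values)
  else if (inherits(x, "Partition")) length(x$labels)
  else if (inherits(x, "phylo")) length(x$tip.label)
  else if (is.data.frame(x)) nrow(x)
  else if (is.matrix(x)) ncol(x)
  else length(x)
}

#' Save and load pipelines as JSON
#'
#' Pipelines serialise to a small JSON document (name, format version,
#' steps) so they can be stored persistently and shared. Loading validates
#' the format version (same major version required) and the steps.
#'
#' @param p a `Pipeline`.
#' @param path file path.
#' @return `load_pipeline`: a validated `Pipeline`.
#' @export
save_pipeline <- function(p, path) {
  stopifnot(inherits(p, "Pipeline"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  major <- as.integer(strsplit(x$format_version %||% "0", ".",
                               fixed = TRUE)[[1L]][1L])
  if (is.na(major) || major > 1L) {
    stop("unsupported pipeline format version: ", x$format_version,
         call. = FALSE)
  }
  pipeline(x$name %||% "pipeline", lapply(x$steps, function(st) {
    st[intersect(names(st), c("op", "params", "input", "output"))]
  }))
}
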