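#' Dynamic probe lists
#'
#' A dynamic probe list is a probe list defined by a filter rule rather than
#' a fixed member set. It caches its members together with the dataset
#' version they were computed from; [refresh_dynamic()] re-evaluates the rule
#' only when the dataset has changed since (lazy recomputation keyed on the
#' version stamp), so unchanged data costs nothing. The `eval_count` field
#' counts actual rule evaluations, which makes the laziness observable.
#'
#' @param name list name.
#' @param rule a `FilterRule`.
#' @return an object of class `DynamicProbeList`.
#' @export
dynamic_probe_list <- function(name, rule) {
  stopifnot(inherits(rule, "FilterRule"))
  structure(list(name = name, rule = rule, members = character(),
                 cached_version = NA_integer_, eval_count = 0L),
            class = "DynamicProbeList")
}

#' @export
print.DynamicProbeList <- function(x, ...) {
  cat(sprintf("<DynamicProbeList '%s'> %d probes matching: %s\n",
              x$name, length(x$members), rule_description(x$rule)))
  invisible(x)
}

#' @rdname dynamic_probe_list
#' @param dpl a `DynamicProbeList`.
#' @param ds the underlying `ExpressionDataSet`.
#' @param context evaluation context (see [evaluate_rule()]).
#' @return the refreshed `DynamicProbeList` (members + version stamp
#'   updated; `eval_count` incremented only if a re-evaluation happened).
#' @export
refresh_dynamic <- function(dpl, ds, context = list()) {
  stopifnot(inherits(dpl, "DynamicProbeList"))
  if (identical(dpl$cached_version, ds$version)) {
    return(dpl)
  }
  pl <- evaluate_rule(dpl$rule, ds, context, name = dpl$name)
  dpl$members <- pl$members
  dpl$cached_version <- ds$version
  dpl$eval_count <- dpl$eval_count + 1L
  message(sprintf("'%s': %d probes match the rule set", dpl$name,
                  length(dpl$members)))
  dpl
}

#' Register a dynamic probe list in an evaluation context
#'
#' Adds the list to `context$probelists` after checking that its rule does
#' not create a dependency cycle through other dynamic lists (membership
#' leaves referencing each other); cycles are rejected at registration.
#'
#' @param context evaluation context list.
#' @param dpl a `DynamicProbeList` (or static `ProbeList`).
#' @return the updated context.
#' @export
register_probelist <- function(context, dpl) {
  if (is.null(context$probelists)) context$probelists <- list()
  context$probelists[[dpl$name]] <- dpl
  if (inherits(dpl, "DynamicProbeList")) {
    check_no_cycles(context)
  }
  context
}

check_no_cycles <- function(context) {
  deps <- lapply(context$probelists, function(pl) {
    if (inherits(pl, "DynamicProbeList")) rule_list_refs(pl$rule) else character()
  })
  visit <- function(name, stack) {
    if (name %in% stack) {
      stop("dependency cycle among dynamic probe lists: ",
           paste(c(stack, name), collapse = " -> "), call. = FALSE)
    }
    for (d in deps[[name]] %||% character()) {
      if (!is.null(deps[[d]])) visit(d, c(stack, name))
    }
  }
  for (nm in names(deps)) visit(nm, character())
  invisible(TRUE)
}

rule_list_refs <- function(rule) {
  if (isTRUE(rule$node)) {
    unique(unlist(lapply(rule$children, rule_list_refs)))
  } else if (rule$kind == "list_membership") {
    rule$list_name
  } else character()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
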