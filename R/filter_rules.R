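#' Boolean filter rules
#'
#' Filter rules form a tree: inner nodes combine children with AND, OR or
#' NOT; leaves test one property of a probe. Available leaf kinds:
#'
#' * `rule_stat()` — a row statistic (`min`, `max`, `mean`, `variance`, or
#'   `value_at` a named experiment) compared to a constant with one of
#'   `<, <=, =, >=, >`;
#' * `rule_meta()` — numeric comparison, string equality or regex match on a
#'   meta-info group; probes without a value for that group fail the leaf;
#' * `rule_name()` — prefix or regex match on the probe identifier;
#' * `rule_in_list()` — membership in a named (possibly dynamic) probe list;
#' * `rule_similar()` — query-by-example: distance to a named example probe
#'   at most `cutoff` under a chosen distance measure.
#'
#' An empty AND group accepts every probe, an empty OR group none (the
#' identity elements of conjunction and disjunction).
#'
#' @param ... child rules (`rule_and`, `rule_or`).
#' @return an object of class `FilterRule`.
#' @name filter_rules
NULL

#' @rdname filter_rules
#' @export
rule_and <- function(...) rule_node("AND", list(...))

#' @rdname filter_rules
#' @export
rule_or <- function(...) rule_node("OR", list(...))

#' @rdname filter_rules
#' @param rule the single child to negate.
#' @export
rule_not <- function(rule) rule_node("NOT", list(rule))

rule_node <- function(op, children) {
  ok <- vapply(children, inherits, logical(1), what = "FilterRule")
  if (!all(ok)) stop("children must be FilterRule objects", call. = FALSE)
  if (op == "NOT" && length(children) != 1L) {
    stop("NOT takes exactly one child", call. = FALSE)
  }
  structure(list(node = TRUE, op = op, children = children),
            class = "FilterRule")
}

rule_leaf <- function(kind, ...) {
  structure(c(list(node = FALSE, kind = kind), list(...)),
            class = "FilterRule")
}

#' @rdname filter_rules
#' @param stat row statistic name.
#' @param cmp comparison operator as string.
#' @param value constant to compare against.
#' @param experiment experiment name, required for `stat = "value_at"`.
#' @export
rule_stat <- function(stat = c("mean", "min", "max", "variance", "value_at"),
                      cmp, value, experiment = NULL) {
  stat <- match.arg(stat)
  check_cmp(cmp)
  if (stat == "value_at" && is.null(experiment)) {
    stop("`value_at` needs an experiment name", call. = FALSE)
  }
  rule_leaf("expression_stat", stat = stat, cmp = cmp,
            value = as.numeric(value), experiment = experiment)
}

#' @rdname filter_rules
#' @param group meta-info group name (resolved in the evaluation context).
#' @param match for string groups: `"equals"` or `"regex"`.
#' @export
rule_meta <- function(group, cmp = NULL, value, match = c("equals", "regex")) {
  match <- match.arg(match)
  if (!is.null(cmp)) check_cmp(cmp)
  rule_leaf("meta_compare", group = group, cmp = cmp, value = value,
            match = match)
}

#' @rdname filter_rules
#' @param pattern prefix text or regular expression.
#' @export
rule_name <- function(pattern, match = c("prefix", "regex")) {
  match <- match.arg(match)
  if (match == "regex") {
    ok <- tryCatch({ suppressWarnings(grepl(pattern, "x")); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("invalid regular expression: ", pattern, call. = FALSE)
  }
  rule_leaf("name_match", pattern = pattern, match = match)
}

#' @rdname filter_rules
#' @param list_name name of a probe list in the evaluation context.
#' @export
rule_in_list <- function(list_name) {
  rule_leaf("list_membership", list_name = list_name)
}

#' @rdname filter_rules
#' @param probe example probe identifier (must exist in the dataset).
#' @param cutoff maximum allowed distance to the example.
#' @param measure a [distance_measure()].
#' @export
rule_similar <- function(probe, cutoff,
                         measure = distance_measure("euclidean")) {
  rule_leaf("similarity", probe = probe, cutoff = as.numeric(cutoff),
            measure = measure)
}

check_cmp <- function(cmp) {
  if (!cmp %in% c("<", "<=", "=", "==", ">=", ">")) {
    stop("unknown comparison operator: ", cmp, call. = FALSE)
  }
}

apply_cmp <- function(x, cmp, value) {
  res <- switch(cmp,
    "<" = x < value, "<=" = x <= value,
    "=" = x == value, "==" = x == value,
    ">=" = x >= value, ">" = x > value)
  res & !is.na(res)
}

#' Evaluate a filter rule against a dataset
#'
#' Returns the probes, in dataset order, for which the rule holds. The
#' `context` supplies named probe lists (static or dynamic) and meta-info
#' groups that leaves may reference; dangling references raise an error.
#' Membership leaves that point at a dynamic probe list are evaluated
#' against that list's freshly refreshed state; dependency cycles among
#' dynamic lists are rejected. Evaluation is pure — the dataset version is
#' never touched.
#'
#' @param rule a `FilterRule`.
#' @param ds an `ExpressionDataSet`.
#' @param context list with optional elements `probelists` (named list of
#'   `ProbeList` / `DynamicProbeList`) and `meta` (named list of
#'   `MetaInfoGroup`).
#' @param name name for the resulting probe list.
#' @return a `ProbeList` in dataset probe order.
#' @export
evaluate_rule <- function(rule, ds, context = list(), name = "filtered") {
  mask <- eval_mask(rule, ds, context, stack = character())
  probe_list(name, probes(ds)[mask])
}

eval_mask <- function(rule, ds, context, stack) {
  stopifnot(inherits(rule, "FilterRule"))
  pn <- probes(ds)
  if (isTRUE(rule$node)) {
    kids <- lapply(rule$children, eval_mask, ds = ds, context = context,
                   stack = stack)
    return(switch(rule$op,
      AND = Reduce(`&`, kids, rep(TRUE, length(pn))),
      OR = Reduce(`|`, kids, rep(FALSE, length(pn))),
      NOT = !kids[[1L]]
    ))
  }
  switch(rule$kind,
    expression_stat = {
      v <- ds$values
      x <- switch(rule$stat,
        mean = rowMeans(v, na.rm = TRUE),
        min = apply(v, 1L, function(r) suppressWarnings(min(r, na.rm = TRUE))),
        max = apply(v, 1L, function(r) suppressWarnings(max(r, na.rm = TRUE))),
        variance = apply(v, 1L, stats::var, na.rm = TRUE),
        value_at = {
          if (!rule$experiment %in% experiments(ds)) {
            stop("unknown experiment: ", rule$experiment, call. = FALSE)
          }
          v[, rule$experiment]
        })
      x[!is.finite(x)] <- NA_real_
      apply_cmp(x, rule$cmp, rule$value)
    },
    meta_compare = {
      mg <- context$meta[[rule$group]]
      if (is.null(mg)) stop("unknown meta group: ", rule$group, call. = FALSE)
      val <- mg$values[pn]
      if (mg$kind == "numeric") {
        apply_cmp(as.numeric(val), rule$cmp, as.numeric(rule$value))
      } else if (identical(rule$match, "regex")) {
        !is.na(val) & grepl(rule$value, val)
      } else {
        !is.na(val) & val == rule$value
      }
    },
    name_match = {
      if (rule$match == "prefix") startsWith(pn, rule$pattern)
      else grepl(rule$pattern, pn)
    },
    list_membership = {
      pl <- context$probelists[[rule$list_name]]
      if (is.null(pl)) stop("unknown probe list: ", rule$list_name, call. = FALSE)
      members <- if (inherits(pl, "DynamicProbeList")) {
        if (rule$list_name %in% stack) {
          stop("dependency cycle through dynamic list '", rule$list_name, "'",
               call. = FALSE)
        }
        probes(ds)[eval_mask(pl$rule, ds, context,
                             stack = c(stack, rule$list_name))]
      } else pl$members
      pn %in% members
    },
    similarity = {
      if (!rule$probe %in% pn) {
        stop("example probe not in dataset: ", rule$probe, call. = FALSE)
      }
      ex <- ds$values[rule$probe, ]
      d <- apply(ds$values, 1L, function(r) {
        tryCatch(profile_distance(r, ex, rule$measure),
                 error = function(e) NA_real_)
      })
      !is.na(d) & d <= rule$cutoff
    },
    stop("unknown rule kind: ", rule$kind, call. = FALSE)
  )
}

#' Human-readable rule description
#'
#' Auto-generates a description string from a rule's content, e.g.
#' `"(name starts with 'SCO' AND strand = '+')"`.
#'
#' @param rule a `FilterRule`.
#' @return a single character string.
#' @export
rule_description <- function(rule) {
  if (isTRUE(rule$node)) {
    if (rule$op == "NOT") {
      return(sprintf("NOT %s", rule_description(rule$children[[1L]])))
    }
    inner <- vapply(rule$children, rule_description, character(1))
    if (!length(inner)) {
      return(if (rule$op == "AND") "(all probes)" else "(no probes)")
    }
    return(sprintf("(%s)", paste(inner, collapse = sprintf(" %s ", rule$op))))
  }
  switch(rule$kind,
    expression_stat = if (rule$stat == "value_at") {
      sprintf("value at '%s' %s %g", rule$experiment, rule$cmp, rule$value)
    } else sprintf("%s %s %g", rule$stat, rule$cmp, rule$value),
    meta_compare = if (is.null(rule$cmp)) {
      sprintf("%s %s '%s'", rule$group,
              if (identical(rule$match, "regex")) "matches" else "=", rule$value)
    } else sprintf("%s %s %s", rule$group, rule$cmp, rule$value),
    name_match = sprintf("name %s '%s'",
                         if (rule$match == "prefix") "starts with" else "matches",
                         rule$pattern),
    list_membership = sprintf("in list '%s'", rule$list_name),
    similarity = sprintf("within %g of '%s' (%s)", rule$cutoff, rule$probe,
                         rule$measure$kind)
  )
}

#' Serialize filter rules to and from JSON
#'
#' Lossless round-trip of a rule tree; the JSON carries the auto-generated
#' description alongside each rule for human inspection. Unknown leaf kinds
#' or operators raise a parse error.
#'
#' @param rule a `FilterRule`.
#' @return `rule_to_json`: a JSON string; `rule_from_json`: a `FilterRule`.
#' @export
rule_to_json <- function(rule) {
  jsonlite::toJSON(rule_to_list(rule), auto_unbox = TRUE, pretty = TRUE,
                   digits = NA)
}

rule_to_list <- function(rule) {
  if (isTRUE(rule$node)) {
    list(op = rule$op, description = rule_description(rule),
         children = lapply(rule$children, rule_to_list))
  } else {
    out <- rule[setdiff(names(rule), c("node", "measure"))]
    out <- Filter(Negate(is.null), out)
    if (!is.null(rule$measure)) {
      out$measure <- list(kind = rule$measure$kind, p = rule$measure$p)
    }
    out$description <- rule_description(rule)
    out
  }
}

#' @rdname rule_to_json
#' @param text JSON text (string or file path contents).
#' @export
rule_from_json <- function(text) {
  rule_from_list(jsonlite::fromJSON(text, simplifyVector = FALSE))
}

rule_from_list <- function(x) {
  if (!is.null(x$op)) {
    if (!x$op %in% c("AND", "OR", "NOT")) {
      stop("unknown operator: ", x$op, call. = FALSE)
    }
    return(rule_node(x$op, lapply(x$children, rule_from_list)))
  }
  switch(as.character(x$kind),
    expression_stat = rule_stat(x$stat, x$cmp, x$value,
                                experiment = x$experiment),
    meta_compare = rule_meta(x$group,
                             cmp = if (length(x$cmp)) x$cmp,
                             value = x$value,
                             match = if (is.null(x$match)) "equals" else x$match),
    name_match = rule_name(x$pattern, x$match),
    list_membership = rule_in_list(x$list_name),
    similarity = rule_similar(x$probe, x$cutoff,
                              distance_measure(x$measure$kind,
                                               p = if (is.null(x$measure$p)) 2 else x$measure$p)),
    stop("unknown rule kind: ", x$kind, call. = FALSE)
  )
}
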