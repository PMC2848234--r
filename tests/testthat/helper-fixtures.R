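# Shared fixtures and independent oracles, built in code at test time.

# tiny dataset with hand-picked values
tiny_ds <- function() {
  m <- matrix(c(1, 2, 3,
                5, 5, 5,
                0, 3, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("SCO0001", "SCO0002", "IGR0001"),
                              c("e1", "e2", "e3")))
  expression_dataset(m, name = "tiny")
}

# random symmetric distance matrix with zero diagonal
rand_dist <- function(n, lo = 0.1, hi = 2) {
  m <- matrix(stats::runif(n * n, lo, hi), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("t", seq_len(n))
  m
}

# three well-separated planted point clusters (10 items each)
planted_blobs <- function(sd = 0.02, per = 10L) {
  centers <- rbind(c(0, 0), c(5, 5), c(10, 0))
  mat <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(stats::rnorm(2 * per, sd = sd), per, 2), 2, centers[k, ], "+")
  }))
  rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  list(mat = mat,
       truth = partition(stats::setNames(rep(1:3, each = per), rownames(mat))))
}

# default synthetic study (quiet)
quiet_synth <- function(...) suppressMessages(generate_synthetic(synthetic_spec(...)))

# ---- independent brute-force rule oracle (per-probe scalar evaluation) ----
brute_rule_holds <- function(rule, probe, ds, ctx) {
  v <- dataset_values(ds)
  if (isTRUE(rule$node)) {
    vals <- vapply(rule$children, brute_rule_holds, logical(1),
                   probe = probe, ds = ds, ctx = ctx)
    return(switch(rule$op,
                  AND = all(vals), OR = any(vals), NOT = !vals[[1]]))
  }
  cmpf <- function(x, cmp, y) {
    if (is.na(x)) return(FALSE)
    switch(cmp, "<" = x < y, "<=" = x <= y, "=" = x == y, "==" = x == y,
           ">=" = x >= y, ">" = x > y)
  }
  row <- v[probe, ]
  switch(rule$kind,
    expression_stat = {
      x <- switch(rule$stat,
                  mean = mean(row, na.rm = TRUE),
                  min = min(row, na.rm = TRUE),
                  max = max(row, na.rm = TRUE),
                  variance = stats::var(row, na.rm = TRUE),
                  value_at = row[[rule$experiment]])
      cmpf(x, rule$cmp, rule$value)
    },
    meta_compare = {
      mg <- ctx$meta[[rule$group]]
      val <- mg$values[probe]
      if (is.na(val) || is.null(val)) return(FALSE)
      if (mg$kind == "numeric") cmpf(as.numeric(val), rule$cmp, as.numeric(rule$value))
      else if (identical(rule$match, "regex")) grepl(rule$value, val)
      else val == rule$value
    },
    name_match = if (rule$match == "prefix") startsWith(probe, rule$pattern)
                 else grepl(rule$pattern, probe),
    list_membership = {
      pl <- ctx$probelists[[rule$list_name]]
      members <- if (inherits(pl, "DynamicProbeList")) {
        ok <- vapply(probes(ds), brute_rule_holds, logical(1),
                     rule = pl$rule, ds = ds, ctx = ctx)
        probes(ds)[ok]
      } else pl$members
      probe %in% members
    },
    similarity = {
      d <- profile_distance(row, v[rule$probe, ], rule$measure)
      d <= rule$cutoff
    })
}

brute_rule_members <- function(rule, ds, ctx) {
  keep <- vapply(probes(ds), brute_rule_holds, logical(1),
                 rule = rule, ds = ds, ctx = ctx)
  probes(ds)[keep]
}

# random rule tree generator for property tests
random_rule <- function(depth, ds) {
  leaf_makers <- list(
    function() rule_stat("mean", sample(c("<", ">=", ">"), 1), stats::runif(1, 0, 4)),
    function() rule_stat("variance", sample(c("<", ">"), 1), stats::runif(1, 0, 2)),
    function() rule_stat("value_at", "<=", stats::runif(1, 0, 4),
                         experiment = sample(experiments(ds), 1)),
    function() rule_name(sample(c("SCO", "IGR", "SCO50"), 1), "prefix"),
    function() rule_meta("strand", value = sample(c("+", "-"), 1)),
    function() rule_meta("start", cmp = sample(c("<", ">="), 1),
                         value = stats::runif(1, 1, 5e4)),
    function() rule_in_list("static_half"),
    function() rule_similar(sample(probes(ds), 1), stats::runif(1, 0.5, 3))
  )
  if (depth <= 0 || stats::runif(1) < 0.35) {
    return(leaf_makers[[sample(length(leaf_makers), 1)]]())
  }
  op <- sample(c("AND", "OR", "NOT"), 1)
  if (op == "NOT") return(rule_not(random_rule(depth - 1, ds)))
  kids <- lapply(seq_len(sample(2:3, 1)), function(i) random_rule(depth - 1, ds))
  if (op == "AND") do.call(rule_and, kids) else do.call(rule_or, kids)
}

# context with annotation meta + one static list over the synthetic dataset
synth_context <- function(syn) {
  ctx <- list(meta = annotation_to_meta(syn$annotation))
  half <- probes(syn$dataset)[seq(1, length(probes(syn$dataset)), by = 2)]
  ctx$probelists <- list(static_half = probe_list("static_half", half))
  ctx
}
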