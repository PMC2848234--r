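#' Specification for synthetic clustered time-series data
#'
#' Describes a synthetic expression study shaped like a dense bacterial
#' fermentation time course: hourly samples starting at 20 h (32 timepoints
#' by default), groups of co-regulated genes switching up or down
#' sigmoidally at successive times around a nutrient-depletion event
#' (defaults: 35, 39 and 43 h), a flat background fraction, and Gaussian
#' measurement noise on the log scale. Signal probes get SCO-style gene
#' names and plus/minus strand annotations; background probes get
#' intergenic-region names.
#'
#' @param n_probes total number of probes.
#' @param n_timepoints number of hourly timepoints.
#' @param t_start first sampling time (hours).
#' @param n_clusters number of co-regulated signal clusters.
#' @param switch_times switch time (hours) per cluster, recycled.
#' @param directions `"up"` or `"down"` per cluster, recycled.
#' @param amplitude log-scale expression change of a switch.
#' @param noise_sd Gaussian noise standard deviation (log scale).
#' @param flat_fraction fraction of probes that are flat background.
#' @param seed mandatory integer RNG seed.
#' @return an object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_probes = 120L, n_timepoints = 32L, t_start = 20,
                           n_clusters = 3L,
                           switch_times = c(35, 39, 43),
                           directions = c("up", "down", "up"),
                           amplitude = 4, noise_sd = 0.1,
                           flat_fraction = 0.25, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n_probes < 1L) stop("need at least 1 probe", call. = FALSE)
  if (n_timepoints < 2L) stop("need at least 2 timepoints", call. = FALSE)
  if (flat_fraction < 0 || flat_fraction > 1) {
    stop("`flat_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!all(directions %in% c("up", "down", "flat"))) {
    stop("directions must be 'up', 'down' or 'flat'", call. = FALSE)
  }
  structure(list(
    n_probes = as.integer(n_probes), n_timepoints = as.integer(n_timepoints),
    t_start = t_start, n_clusters = as.integer(n_clusters),
    switch_times = rep_len(switch_times, n_clusters),
    directions = rep_len(directions, n_clusters),
    amplitude = amplitude, noise_sd = noise_sd,
    flat_fraction = flat_fraction, seed = as.integer(seed)
  ), class = "SyntheticSpec")
}

# noiseless cluster mean profile at times t (hours): sigmoid switch
switch_profile <- function(t, t_switch, direction, amplitude, steepness = 1.5) {
  base <- amplitude / (1 + exp(-steepness * (t - t_switch)))
  switch(direction, up = base, down = amplitude - base,
         flat = rep(amplitude / 2, length(t)))
}

#' Generate a synthetic clustered expression time series
#'
#' Builds an `ExpressionDataSet` from a [synthetic_spec()] together with the
#' embedded ground truth: the true cluster partition (background probes form
#' their own cluster), genomic annotation records (sequential 1-based loci
#' on a circular-chromosome-sized replicon, alternating strand) and the true
#' switch times. Deterministic given the spec's seed.
#'
#' @param spec a `SyntheticSpec`.
#' @return list with `dataset`, `truth` (a `Partition`), `annotation`
#'   (an `AnnotationRecord` data frame), `switch_times`, `cluster_of`
#'   (named integer vector, 0 = background).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))

  times <- spec$t_start + seq_len(spec$n_timepoints) - 1
  n_flat <- round(spec$n_probes * spec$flat_fraction)
  n_signal <- spec$n_probes - n_flat
  cluster_of <- integer(spec$n_probes)
  if (n_signal > 0L && spec$n_clusters > 0L) {
    cluster_of[seq_len(n_signal)] <- rep_len(seq_len(spec$n_clusters), n_signal)
  }
  # names: signal probes look like protein-coding genes, background like
  # intergenic probes
  pn <- character(spec$n_probes)
  sig_idx <- which(cluster_of > 0L)
  bg_idx <- which(cluster_of == 0L)
  pn[sig_idx] <- sprintf("SCO%04d", 5070 + seq_along(sig_idx))
  pn[bg_idx] <- sprintf("IGR%04d", seq_along(bg_idx))

  vals <- matrix(NA_real_, spec$n_probes, spec$n_timepoints,
                 dimnames = list(pn, sprintf("T%02dh", times)))
  for (i in seq_len(spec$n_probes)) {
    cl <- cluster_of[i]
    mu <- if (cl == 0L) {
      rep(stats::runif(1, 0, spec$amplitude), spec$n_timepoints)
    } else {
      switch_profile(times, spec$switch_times[cl], spec$directions[cl],
                     spec$amplitude)
    }
    vals[i, ] <- mu + stats::rnorm(spec$n_timepoints, sd = spec$noise_sd)
  }
  ds <- expression_dataset(vals, name = "synthetic", times = times)

  width <- 900L
  start <- 1L + (seq_len(spec$n_probes) - 1L) * 1000L
  ann <- annotation_records(pn, rep("chromosome", spec$n_probes),
                            start, start + width,
                            ifelse(seq_len(spec$n_probes) %% 2L == 1L, "+", "-"))
  truth <- partition(stats::setNames(cluster_of + 1L, pn))  # background = 1
  list(dataset = ds, truth = truth, annotation = ann,
       switch_times = spec$switch_times,
       cluster_of = stats::setNames(cluster_of, pn))
}

#' Generate a pair of replicate time courses with a known time shift
#'
#' Emulates two fermentation runs of the same organism in which the second
#' run executes the transcriptional program `shift_steps` grid steps later
#' (e.g. delayed nutrient depletion). The underlying noiseless profiles are
#' evaluated on the shifted time grid, so the shift is exact by
#' construction; independent noise is added to both replicates.
#'
#' @param spec a `SyntheticSpec`.
#' @param shift_steps signed integer shift of the second replicate
#'   (`|shift| <` number of timepoints).
#' @param extra_noise_sd additional noise sd for the second replicate.
#' @return list with `dsA`, `dsB` (query, delayed by `shift_steps`), `truth`.
#' @export
generate_replicate_pair <- function(spec, shift_steps = 1L,
                                    extra_noise_sd = 0) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (abs(shift_steps) >= spec$n_timepoints) {
    stop("|shift| must be smaller than the number of timepoints", call. = FALSE)
  }
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))

  times <- spec$t_start + seq_len(spec$n_timepoints) - 1
  n_flat <- round(spec$n_probes * spec$flat_fraction)
  n_signal <- spec$n_probes - n_flat
  cluster_of <- integer(spec$n_probes)
  if (n_signal > 0L && spec$n_clusters > 0L) {
    cluster_of[seq_len(n_signal)] <- rep_len(seq_len(spec$n_clusters), n_signal)
  }
  pn <- sprintf("P%04d", seq_len(spec$n_probes))
  mk <- function(t_eval, noise_sd, tag) {
    vals <- matrix(NA_real_, spec$n_probes, spec$n_timepoints,
                   dimnames = list(pn, sprintf("T%02dh", times)))
    for (i in seq_len(spec$n_probes)) {
      cl <- cluster_of[i]
      mu <- if (cl == 0L) {
        rep(spec$amplitude / 2, spec$n_timepoints)
      } else {
        switch_profile(t_eval, spec$switch_times[cl], spec$directions[cl],
                       spec$amplitude)
      }
      vals[i, ] <- mu + if (noise_sd > 0) {
        stats::rnorm(spec$n_timepoints, sd = noise_sd)
      } else 0
    }
    expression_dataset(vals, name = tag, times = times)
  }
  dsA <- mk(times, spec$noise_sd, "F199")
  dsB <- mk(times - shift_steps, sqrt(spec$noise_sd^2 + extra_noise_sd^2),
            "F202")
  list(dsA = dsA, dsB = dsB,
       truth = list(shift = as.integer(shift_steps),
                    cluster_of = stats::setNames(cluster_of, pn)))
}
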