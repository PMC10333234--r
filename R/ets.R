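#' Edge time series of a run
#'
#' Z-scores every parcel over the full run using the population standard
#' deviation and forms, for every parcel pair (i, j) with i < j, the
#' per-frame product z_i(t) * z_j(t). The time-mean of each edge's trace
#' equals the full-run Pearson correlation of that pair exactly (a
#' consequence of population z-scoring), so the ETS is an exact temporal
#' decomposition of functional connectivity.
#'
#' @param run a [parcellated_run()] whose parcels all have nonzero variance.
#' @return object of class `edge_time_series` with `values` (time x edge
#'   matrix), `edge_index` (see [edge_index()]) and the source run key.
#' @export
compute_ets <- function(run) {
  stopifnot(inherits(run, "parcellated_run"))
  x <- run$data
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  if (any(sds == 0))
    stop("zero-variance parcel(s): ", paste(which(sds == 0), collapse = ", "))
  z <- sweep(sweep(x, 2, colMeans(x)), 2, sds, "/")
  idx <- edge_index(run$n_parcels)
  values <- z[, idx$i, drop = FALSE] * z[, idx$j, drop = FALSE]
  colnames(values) <- idx$label
  structure(list(values = values, edge_index = idx,
                 run_key = sprintf("%s_d%d_%s", run$subject_id, run$day,
                                   run$encoding)),
            class = "edge_time_series")
}

#' Root-sum-of-squares co-fluctuation amplitude
#'
#' RSS(t) = sqrt(sum over edges of ETS(t, e)^2): the global co-fluctuation
#' amplitude of the brain at frame t. High-RSS frames are the
#' high-amplitude co-fluctuation (HACF) "events", low-RSS frames the LACF
#' regime.
#'
#' @param ets an [compute_ets()] result.
#' @return object of class `rss_trace` with nonnegative `values`, one per
#'   frame.
#' @export
compute_rss <- function(ets) {
  stopifnot(inherits(ets, "edge_time_series"))
  structure(list(values = sqrt(rowSums(ets$values^2)),
                 run_key = ets$run_key), class = "rss_trace")
}

#' Rank frames by co-fluctuation amplitude
#'
#' @param rss an [compute_rss()] trace or numeric vector.
#' @return integer permutation of frame indices in descending RSS order;
#'   ties broken by ascending frame index (stable).
#' @export
rank_time_points <- function(rss) {
  v <- if (inherits(rss, "rss_trace")) rss$values else rss
  order(-v, seq_along(v))
}

#' Specify a time-point sampling strategy
#'
#' Three strategies select frames from the RSS ranking: `sequential_hacf` /
#' `sequential_lacf` take the top / bottom `threshold_pct` percent of
#' frames; `individual_bin` takes one of `n_bins` equal-sized rank bins
#' (bin 1 = highest co-fluctuation); `combined_bins` the union of two bins;
#' `full` all frames.
#'
#' @param strategy one of `"sequential_hacf"`, `"sequential_lacf"`,
#'   `"individual_bin"`, `"combined_bins"`, `"full"`.
#' @param threshold_pct percentage of frames for sequential strategies, in
#'   (0, 100\].
#' @param bin bin index for `individual_bin`, 1..n_bins.
#' @param bin_pair two bin indices `c(b1, b2)` with b1 < b2 for
#'   `combined_bins`.
#' @param n_bins number of rank bins (20 for 1200-frame runs, 8 for
#'   440-frame runs).
#' @return object of class `sampling_spec`.
#' @export
sampling_spec <- function(strategy = c("sequential_hacf", "sequential_lacf",
                                       "individual_bin", "combined_bins", "full"),
                          threshold_pct = NULL, bin = NULL, bin_pair = NULL,
                          n_bins = 20L) {
  strategy <- match.arg(strategy)
  spec <- list(strategy = strategy, n_bins = as.integer(n_bins))
  if (strategy %in% c("sequential_hacf", "sequential_lacf")) {
    if (is.null(threshold_pct) || threshold_pct <= 0 || threshold_pct > 100)
      stop("sequential sampling needs threshold_pct in (0, 100]")
    spec$threshold_pct <- threshold_pct
  } else if (strategy == "individual_bin") {
    if (is.null(bin) || bin < 1 || bin > n_bins)
      stop("individual_bin needs bin in 1..n_bins")
    spec$bin <- as.integer(bin)
  } else if (strategy == "combined_bins") {
    if (is.null(bin_pair) || length(bin_pair) != 2 ||
        bin_pair[1] >= bin_pair[2] || any(bin_pair < 1) || any(bin_pair > n_bins))
      stop("combined_bins needs bin_pair = c(b1, b2) with 1 <= b1 < b2 <= n_bins")
    spec$bin_pair <- as.integer(bin_pair)
  }
  structure(spec, class = "sampling_spec")
}

# short human-readable label used in provenance and result keys
spec_label <- function(spec) {
  switch(spec$strategy,
         sequential_hacf = sprintf("hacf%g", spec$threshold_pct),
         sequential_lacf = sprintf("lacf%g", spec$threshold_pct),
         individual_bin = sprintf("bin%d_of%d", spec$bin, spec$n_bins),
         combined_bins = sprintf("bins%d+%d_of%d", spec$bin_pair[1],
                                 spec$bin_pair[2], spec$n_bins),
         full = "full")
}

#' Select frames from an RSS ranking
#'
#' @param ranking permutation from [rank_time_points()].
#' @param spec a [sampling_spec()].
#' @return integer vector of selected frame indices in ascending time
#'   order.
#' @export
select_time_points <- function(ranking, spec) {
  stopifnot(inherits(spec, "sampling_spec"))
  n_t <- length(ranking)
  pick <- switch(
    spec$strategy,
    full = ranking,
    sequential_hacf = ,
    sequential_lacf = {
      k <- floor(spec$threshold_pct / 100 * n_t)
      if (k < 2)
        stop(sprintf("threshold %g%% of %d frames yields %d < 2 points",
                     spec$threshold_pct, n_t, k))
      if (spec$strategy == "sequential_hacf") ranking[seq_len(k)]
      else ranking[seq.int(n_t - k + 1L, n_t)]
    },
    individual_bin = ,
    combined_bins = {
      if (n_t %% spec$n_bins != 0)
        stop(sprintf("%d frames cannot be divided into %d equal bins",
                     n_t, spec$n_bins))
      w <- n_t %/% spec$n_bins
      bin_idx <- function(b) ranking[seq.int((b - 1L) * w + 1L, b * w)]
      if (spec$strategy == "individual_bin") bin_idx(spec$bin)
      else c(bin_idx(spec$bin_pair[1]), bin_idx(spec$bin_pair[2]))
    })
  sort(pick)
}

#' Functional connectivity matrix
#'
#' Symmetric Pearson-correlation matrix with unit diagonal and its
#' canonical upper-triangle vectorisation.
#'
#' @param matrix symmetric correlation matrix.
#' @param provenance named list recording subject / sampling spec /
#'   aggregation level.
#' @return object of class `fc_matrix` with fields `matrix`, `vec` (in
#'   [edge_index()] order) and `provenance`.
#' @export
fc_matrix <- function(matrix, provenance = list()) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  structure(list(matrix = matrix, vec = upper_vec(matrix),
                 provenance = provenance), class = "fc_matrix")
}

#' Estimate FC from a subset of frames
#'
#' Pearson correlation between every pair of parcels using only the
#' selected frames, with means and standard deviations recomputed on that
#' subset. A parcel constant over the subset gets zero correlations with a
#' warning.
#'
#' @param run a [parcellated_run()].
#' @param indices frame indices to include (>= 3, within range); `NULL` for
#'   all frames.
#' @return an [fc_matrix()].
#' @export
estimate_fc <- function(run, indices = NULL) {
  stopifnot(inherits(run, "parcellated_run"))
  if (is.null(indices)) indices <- seq_len(run$n_timepoints)
  if (length(indices) < 3) stop("need at least 3 selected frames")
  if (any(indices < 1) || any(indices > run$n_timepoints))
    stop("frame indices out of range")
  x <- run$data[indices, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0
  m <- matrix(0, ncol(x), ncol(x))
  if (any(const)) {
    warning("parcel(s) constant over the selected frames, correlations set to 0: ",
            paste(which(const), collapse = ", "))
    if (sum(!const) >= 2)
      m[!const, !const] <- stats::cor(x[, !const, drop = FALSE])
  } else {
    m <- stats::cor(x)
  }
  diag(m) <- 1
  fc_matrix(m, provenance = list(subject = run$subject_id, day = run$day,
                                 encoding = run$encoding,
                                 n_frames = length(indices)))
}

#' Sample a run with a strategy and estimate its FC
#'
#' Convenience wrapper: ETS -> RSS -> ranking -> frame selection -> Pearson
#' FC on the selected frames.
#'
#' @param run a [parcellated_run()].
#' @param spec a [sampling_spec()].
#' @return an [fc_matrix()] with the spec label in its provenance.
#' @export
sampled_fc <- function(run, spec) {
  ranking <- rank_time_points(compute_rss(compute_ets(run)))
  fc <- estimate_fc(run, select_time_points(ranking, spec))
  fc$provenance$spec <- spec_label(spec)
  fc
}

#' Average FC matrices across runs
#'
#' Element-wise mean of per-run FC. `per_day` averages over phase-encoding
#' directions only, leaving two matrices per subject (the identification
#' input); `per_subject` averages over all runs, leaving one (the
#' prediction input). Raw correlations are averaged (no Fisher transform)
#' unless `fisher = TRUE`.
#'
#' @param fcs list of [fc_matrix()] objects whose provenance carries
#'   `subject`, `day` and a common sampling spec.
#' @param level `"per_day"` or `"per_subject"`.
#' @param fisher average in Fisher-z space.
#' @return named list of `fc_matrix` (keys `<subject>_d<day>` or
#'   `<subject>`).
#' @export
aggregate_fc <- function(fcs, level = c("per_day", "per_subject"),
                         fisher = FALSE) {
  level <- match.arg(level)
  key_of <- function(fc) {
    if (level == "per_day")
      sprintf("%s_d%d", fc$provenance$subject, fc$provenance$day)
    else fc$provenance$subject
  }
  keys <- vapply(fcs, key_of, character(1))
  out <- lapply(split(fcs, keys), function(grp) {
    ms <- lapply(grp, function(fc) {
      if (fisher) atanh(pmin(pmax(fc$matrix, -1 + 1e-15), 1 - 1e-15))
      else fc$matrix
    })
    m <- Reduce(`+`, ms) / length(ms)
    if (fisher) m <- tanh(m)
    diag(m) <- 1
    prov <- grp[[1]]$provenance
    prov$level <- level
    prov$n_averaged <- length(ms)
    if (level == "per_subject") prov$day <- NULL
    prov$encoding <- NULL
    fc_matrix(m, provenance = prov)
  })
  out[unique(keys)]
}
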