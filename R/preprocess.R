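#' Nuisance time-series for one run
#'
#' Bundles the mean white-matter (WM), cerebrospinal-fluid (CSF) and global
#' signal (GS) time courses and the framewise displacement (FD) trace of a
#' run, with the motion-spike threshold used to build spike regressors.
#'
#' @param wm,csf,gs nuisance mean time courses, one value per frame.
#' @param fd framewise displacement in mm, one nonnegative value per frame.
#' @param fd_spike_threshold FD above which a frame receives a one-hot spike
#'   regressor, in mm.
#' @return object of class `confound_set`.
#' @export
confound_set <- function(wm, csf, gs, fd, fd_spike_threshold = 0.25) {
  n <- length(wm)
  if (length(csf) != n || length(gs) != n || length(fd) != n)
    stop("wm, csf, gs and fd must all have the same length")
  if (any(fd < 0)) stop("fd must be nonnegative")
  structure(list(wm = wm, csf = csf, gs = gs, fd = fd,
                 fd_spike_threshold = fd_spike_threshold),
            class = "confound_set")
}

#' Build the nuisance design matrix for a run
#'
#' For each of WM, CSF and GS: the series itself, its square, its backward
#' temporal difference (first element 0) and the squared difference — 12
#' labelled columns in total. One binary one-hot spike column is then
#' appended for every frame whose FD exceeds the threshold; spike columns
#' are extras, not part of the 12-parameter count.
#'
#' @param confounds a [confound_set()].
#' @return numeric matrix, time x (12 + number of supra-threshold frames),
#'   with column names like `wm`, `wm_sq`, `wm_dt`, `wm_dt_sq`,
#'   `spike_<frame>`.
#' @export
build_confound_design <- function(confounds) {
  stopifnot(inherits(confounds, "confound_set"))
  bdiff <- function(x) c(0, diff(x))
  cols <- list()
  for (nm in c("wm", "csf", "gs")) {
    x <- confounds[[nm]]
    d <- bdiff(x)
    cols[[nm]] <- x
    cols[[paste0(nm, "_sq")]] <- x^2
    cols[[paste0(nm, "_dt")]] <- d
    cols[[paste0(nm, "_dt_sq")]] <- d^2
  }
  design <- do.call(cbind, cols)
  spikes <- which(confounds$fd > confounds$fd_spike_threshold)
  if (length(spikes)) {
    sp <- matrix(0, nrow(design), length(spikes),
                 dimnames = list(NULL, paste0("spike_", spikes)))
    sp[cbind(spikes, seq_along(spikes))] <- 1
    design <- cbind(design, sp)
  }
  design
}

# zero-phase Butterworth bandpass applied column-wise
bandpass_cols <- function(m, band, tr, order = 5L) {
  nyq <- 1 / (2 * tr)
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop(sprintf("band (%g, %g) Hz infeasible for tr = %g s (Nyquist %g Hz)",
                 band[1], band[2], tr, nyq))
  bf <- signal::butter(order, band / nyq, type = "pass")
  apply(m, 2, function(x) signal::filtfilt(bf, x))
}

# drop collinear columns by pivoted QR, warning with the dropped labels
drop_collinear <- function(x) {
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop <- qx$pivot[seq.int(qx$rank + 1L, ncol(x))]
    warning("rank-deficient design; dropping collinear column(s): ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, -drop, drop = FALSE]
  }
  x
}

#' Clean a parcellated run
#'
#' Per parcel: remove the linear trend, zero-phase bandpass filter
#' (Butterworth, `filter_order` poles per pass) in `band`, and regress out
#' the nuisance design by least squares. Continuous design columns are
#' detrended and filtered identically before regression so the confound
#' removal cannot re-introduce out-of-band signal and the output is exactly
#' orthogonal to the processed design; binary spike columns (names starting
#' `spike_`) are left unfiltered.
#'
#' @param run a [parcellated_run()].
#' @param design optional nuisance design matrix from
#'   [build_confound_design()] (time x columns); `NULL` for none.
#' @param band bandpass edges in Hz, `c(low, high)`, default the standard
#'   resting-state band 0.008-0.08 Hz; `NULL` skips filtering.
#' @param detrend remove the per-parcel linear trend first (default TRUE).
#' @param filter_order Butterworth order per pass.
#' @return a cleaned `parcellated_run` of identical shape.
#' @export
clean_run <- function(run, design = NULL, band = c(0.008, 0.08),
                      detrend = TRUE, filter_order = 5L) {
  stopifnot(inherits(run, "parcellated_run"))
  x <- run$data
  n <- nrow(x)
  if (!is.null(design)) {
    design <- as.matrix(design)
    if (nrow(design) != n)
      stop(sprintf("design has %d rows but the run has %d time points",
                   nrow(design), n))
  }
  detrend_cols <- function(m) {
    tt <- cbind(1, seq_len(n))
    m - tt %*% qr.solve(tt, m)
  }
  if (detrend) x <- detrend_cols(x)
  if (!is.null(band)) x <- bandpass_cols(x, band, run$tr, filter_order)
  if (!is.null(design) && ncol(design)) {
    is_spike <- grepl("^spike_", colnames(design) %||% rep("", ncol(design)))
    d <- design
    if (any(!is_spike)) {
      dc <- d[, !is_spike, drop = FALSE]
      if (detrend) dc <- detrend_cols(dc)
      if (!is.null(band)) dc <- bandpass_cols(dc, band, run$tr, filter_order)
      d[, !is_spike] <- dc
    }
    d <- cbind(intercept = 1, d)
    d <- drop_collinear(d)
    x <- x - d %*% qr.solve(d, x)
  }
  parcellated_run(x, tr = run$tr, subject_id = run$subject_id,
                  day = run$day, encoding = run$encoding)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlate co-fluctuation amplitude with head motion
#'
#' Pearson correlation between a run's RSS trace and its framewise
#' displacement. Under clean data this should be centred on zero across a
#' cohort; a shifted distribution flags motion-driven co-fluctuation
#' events.
#'
#' @param rss an [rss_trace()] or numeric RSS vector.
#' @param fd framewise displacement trace of the same length.
#' @return correlation coefficient.
#' @export
rss_motion_correlation <- function(rss, fd) {
  v <- if (inherits(rss, "rss_trace")) rss$values else rss
  if (length(v) != length(fd)) stop("rss and fd must have equal length")
  pearson_r(v, fd)
}
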