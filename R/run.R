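#' A single parcellated BOLD run
#'
#' Container for one subject-run time-series matrix (time points in rows,
#' parcels in columns) together with its acquisition metadata. All runs of a
#' cohort share a fixed parcel order, so column k always refers to the same
#' brain area.
#'
#' @param data numeric matrix, time x parcels, no missing values.
#' @param tr repetition time in seconds (sampling interval).
#' @param subject_id subject identifier.
#' @param day scan day, 1 or 2.
#' @param encoding phase-encoding direction label, "A" or "B".
#' @return object of class `parcellated_run` with fields `data`, `tr`,
#'   `subject_id`, `day`, `encoding`, `n_timepoints`, `n_parcels`.
#' @export
parcellated_run <- function(data, tr, subject_id = NA_character_,
                            day = 1L, encoding = "A") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("run data must be numeric")
  if (anyNA(data)) {
    bad <- which(is.na(data), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value in run data at row %d, column %d",
                 bad[1L], bad[2L]))
  }
  if (nrow(data) < 3) stop("a run needs at least 3 time points")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be a positive number of seconds")
  if (!day %in% c(1L, 2L)) stop("day must be 1 or 2")
  if (!encoding %in% c("A", "B")) stop("encoding must be \"A\" or \"B\"")
  structure(
    list(data = data, tr = tr, subject_id = as.character(subject_id),
         day = as.integer(day), encoding = encoding,
         n_timepoints = nrow(data), n_parcels = ncol(data)),
    class = "parcellated_run")
}

#' @export
print.parcellated_run <- function(x, ...) {
  cat(sprintf("<parcellated_run> subject %s day %d enc %s: %d time points x %d parcels (tr = %gs)\n",
              x$subject_id, x$day, x$encoding, x$n_timepoints, x$n_parcels, x$tr))
  invisible(x)
}

#' Trim frames from the start and end of a run
#'
#' Drops `head` leading and `tail` trailing volumes, e.g. to shorten a
#' 478-frame acquisition to 440 frames that divide evenly into ranked
#' co-fluctuation bins.
#'
#' @param run a [parcellated_run()].
#' @param head number of leading frames to drop.
#' @param tail number of trailing frames to drop.
#' @return a `parcellated_run` with `n_timepoints - head - tail` frames.
#' @export
trim_run <- function(run, head = 0L, tail = 0L) {
  stopifnot(inherits(run, "parcellated_run"))
  head <- as.integer(head); tail <- as.integer(tail)
  if (head < 0 || tail < 0) stop("head and tail must be nonnegative")
  n <- run$n_timepoints
  if (head + tail >= n)
    stop(sprintf("cannot trim %d + %d frames from a run of length %d",
                 head, tail, n))
  keep <- seq.int(head + 1L, n - tail)
  parcellated_run(run$data[keep, , drop = FALSE], tr = run$tr,
                  subject_id = run$subject_id, day = run$day,
                  encoding = run$encoding)
}
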