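#' Write a parcellated run to delimited text
#'
#' The time x parcel matrix goes to a tab-delimited file and the
#' acquisition metadata (tr, subject, day, encoding) to a JSON sidecar at
#' `<path>.json`.
#'
#' @param run a [parcellated_run()].
#' @param path output file path (e.g. `"s01_d1_A.tsv"`).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(run, path) {
  stopifnot(inherits(run, "parcellated_run"))
  utils::write.table(run$data, path, sep = "\t", row.names = FALSE,
                     col.names = paste0("p", seq_len(run$n_parcels)))
  jsonlite::write_json(list(tr = run$tr, subject_id = run$subject_id,
                            day = run$day, encoding = run$encoding),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a parcellated run from delimited text
#'
#' Reads the matrix written by [write_timeseries()] and its JSON metadata
#' sidecar, validating shape and completeness.
#'
#' @param path path to the delimited matrix; `<path>.json` must exist.
#' @return a [parcellated_run()].
#' @export
load_timeseries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  if (!is.numeric(m)) stop("non-numeric values in ", path)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("NaN/missing value in %s at row %d, column %d",
                 path, bad[1L], bad[2L]))
  }
  parcellated_run(m, tr = meta$tr, subject_id = meta$subject_id,
                  day = meta$day, encoding = meta$encoding)
}

#' Write a cohort to a directory of delimited text files
#'
#' Layout: `runs/<key>.tsv` (+ JSON sidecars), `fd/<key>.tsv`,
#' `phenotypes.tsv`, `confounds.tsv`, `families.tsv`, `sc/<subject>.tsv`,
#' `truth/sigma_<subject>.tsv` and a `manifest.json` naming subjects, run
#' keys, families and a numeric digest of the ground truth.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  for (d in c("", "runs", "fd", "sc", "truth"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$runs))
    write_timeseries(cohort$runs[[key]], file.path(dir, "runs", paste0(key, ".tsv")))
  for (key in names(cohort$fd))
    utils::write.table(data.frame(fd = cohort$fd[[key]]),
                       file.path(dir, "fd", paste0(key, ".tsv")),
                       sep = "\t", row.names = FALSE)
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", row.names = FALSE)
  utils::write.table(cohort$confounds, file.path(dir, "confounds.tsv"),
                     sep = "\t", row.names = FALSE)
  utils::write.table(data.frame(subject = names(cohort$families),
                                family = as.integer(cohort$families)),
                     file.path(dir, "families.tsv"), sep = "\t",
                     row.names = FALSE)
  for (sb in names(cohort$sc %||% list()))
    utils::write.table(cohort$sc[[sb]]$matrix,
                       file.path(dir, "sc", paste0(sb, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  truth_digest <- NULL
  if (!is.null(cohort$truth)) {
    for (sb in names(cohort$truth$sigma))
      utils::write.table(cohort$truth$sigma[[sb]],
                         file.path(dir, "truth", paste0("sigma_", sb, ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    truth_digest <- vapply(cohort$truth$sigma, function(s)
      round(sum(s), 10), numeric(1))
  }
  jsonlite::write_json(
    list(subjects = cohort_subjects(cohort), runs = names(cohort$runs),
         families = as.list(cohort$families), truth_digest = truth_digest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `synthetic_cohort` (with `truth$sigma` restored when present;
#'   generator internals such as gain traces are not round-tripped).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  runs <- lapply(manifest$runs, function(key)
    load_timeseries(file.path(dir, "runs", paste0(key, ".tsv"))))
  names(runs) <- manifest$runs
  fd <- lapply(manifest$runs, function(key)
    utils::read.table(file.path(dir, "fd", paste0(key, ".tsv")),
                      header = TRUE, sep = "\t")$fd)
  names(fd) <- manifest$runs
  phenotypes <- utils::read.table(file.path(dir, "phenotypes.tsv"),
                                  header = TRUE, sep = "\t")
  confounds <- utils::read.table(file.path(dir, "confounds.tsv"),
                                 header = TRUE, sep = "\t")
  fam_tab <- utils::read.table(file.path(dir, "families.tsv"),
                               header = TRUE, sep = "\t")
  families <- stats::setNames(as.integer(fam_tab$family), fam_tab$subject)
  sc <- NULL
  sc_files <- list.files(file.path(dir, "sc"), pattern = "\\.tsv$")
  if (length(sc_files)) {
    sc <- lapply(sc_files, function(f)
      sc_matrix(as.matrix(utils::read.table(file.path(dir, "sc", f), sep = "\t"))))
    names(sc) <- sub("\\.tsv$", "", sc_files)
  }
  truth <- NULL
  tr_files <- list.files(file.path(dir, "truth"), pattern = "^sigma_.*\\.tsv$")
  if (length(tr_files)) {
    sigma <- lapply(tr_files, function(f)
      as.matrix(utils::read.table(file.path(dir, "truth", f), sep = "\t")))
    names(sigma) <- sub("^sigma_(.*)\\.tsv$", "\\1", tr_files)
    truth <- list(sigma = sigma[manifest$subjects])
  }
  structure(list(runs = runs, phenotypes = phenotypes, confounds = confounds,
                 fd = fd, families = families, sc = sc, truth = truth,
                 config = NULL), class = "synthetic_cohort")
}
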