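# shared fixtures: everything is generated in code, no data files

rand_run <- function(n_t = 50, p = 6, seed = 1, tr = 0.72, ...) {
  set.seed(seed)
  parcellated_run(matrix(rnorm(n_t * p), n_t, p), tr = tr, ...)
}

# independent covariance-based Pearson implementation used as oracle
ref_pearson <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# per-subject FC feature rows (mean over all runs) from a cohort
cohort_features <- function(cohort) {
  subj <- cohort_subjects(cohort)
  t(vapply(subj, function(s) {
    keys <- grep(paste0("^", s, "_"), names(cohort$runs), value = TRUE)
    rowMeans(vapply(keys, function(k) estimate_fc(cohort$runs[[k]])$vec,
                    numeric(length(estimate_fc(cohort$runs[[keys[1]]])$vec))))
  }, numeric(length(estimate_fc(cohort$runs[[1]])$vec))))
}

# per-day averaged FC rows for fingerprinting
cohort_day_fc <- function(cohort, day) {
  subj <- cohort_subjects(cohort)
  fcs <- lapply(names(cohort$runs), function(k) estimate_fc(cohort$runs[[k]]))
  per_day <- aggregate_fc(fcs, "per_day")
  m <- t(vapply(subj, function(s) per_day[[sprintf("%s_d%d", s, day)]]$vec,
                numeric(length(per_day[[1]]$vec))))
  rownames(m) <- subj
  m
}
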