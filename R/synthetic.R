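#' Configuration for a synthetic multi-subject BOLD cohort
#'
#' Describes the statistical structure of a simulated resting-state cohort:
#' every subject owns a stable covariance fingerprint (a blend of a shared
#' population covariance, a family-level perturbation and a subject-level
#' perturbation, weighted by `subject_snr`), each run overlays transient
#' brain-wide co-fluctuation events as a multiplicative gain on the latent
#' signal, and phenotypes are linear in the subject's true FC edges plus a
#' confound contribution plus noise.
#'
#' `n_timepoints` should be chosen divisible by every bin count the
#' downstream binned sampling will request (e.g. 120 works for 20, 8, 6 or
#' 4 bins).
#'
#' @param n_subjects,n_parcels,n_timepoints cohort dimensions (all >= 1;
#'   `n_parcels` >= 2, `n_timepoints` >= 3).
#' @param n_runs runs per subject: 4 (two days x two phase encodings, the
#'   default) or 2 (one encoding per day).
#' @param tr repetition time in seconds.
#' @param subject_snr weight of the subject-specific covariance perturbation
#'   relative to the shared population covariance; 0 makes all subjects
#'   statistically identical.
#' @param event_rate expected number of co-fluctuation events per run
#'   (Poisson).
#' @param event_amplitude gain excess during an event; the latent signal is
#'   scaled by `1 + event_amplitude` inside a burst, 1 elsewhere.
#' @param event_duration event length in frames.
#' @param noise_sd standard deviation of additive observation noise.
#' @param n_families number of families; family members share the
#'   family-level covariance perturbation and must be kept together in
#'   grouped cross-validation.
#' @param family_strength mixing weight of the family perturbation within a
#'   subject's covariance deviation, in \[0, 1\].
#' @param rss_fd_coupling coupling of framewise displacement to the event
#'   gain; 0 (default) gives motion independent of co-fluctuation amplitude,
#'   positive values induce an RSS-FD correlation for diagnostics testing.
#' @param target_spec list of phenotype specifications, each a numeric
#'   vector `c(n_informative_edges, effect_size, confound_weight)` with an
#'   optional 4th element giving the target noise sd (default 1; 0 gives a
#'   noise-free phenotype).
#' @param seed integer seed; together with the config it fully determines
#'   the generated cohort.
#' @return object of class `cohort_config`.
#' @seealso [generate_cohort()], [make_fixture()]
#' @export
cohort_config <- function(n_subjects, n_parcels, n_timepoints, n_runs = 4L,
                          tr = 0.72, subject_snr = 1, event_rate = 3,
                          event_amplitude = 1, event_duration = 5L,
                          noise_sd = 0.5, n_families = n_subjects,
                          family_strength = 0.5, rss_fd_coupling = 0,
                          target_spec = list(c(10, 1, 0.3)), seed = 1L) {
  chk_count <- function(x, name, min = 1L) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
      stop(sprintf("invalid config field '%s': must be an integer >= %d", name, min))
  }
  chk_count(n_subjects, "n_subjects", 2L)
  chk_count(n_parcels, "n_parcels", 2L)
  chk_count(n_timepoints, "n_timepoints", 3L)
  if (!n_runs %in% c(2L, 4L))
    stop("invalid config field 'n_runs': must be 2 or 4 (runs split over two days)")
  chk_count(n_families, "n_families")
  chk_count(event_duration, "event_duration")
  if (n_families > n_subjects)
    stop("invalid config field 'n_families': cannot exceed n_subjects")
  for (f in c("tr", "subject_snr", "event_rate", "event_amplitude", "noise_sd")) {
    v <- get(f)
    if (length(v) != 1 || !is.finite(v) || v < 0)
      stop(sprintf("invalid config field '%s': must be a nonnegative scalar", f))
  }
  if (tr <= 0) stop("invalid config field 'tr': must be positive")
  if (family_strength < 0 || family_strength > 1)
    stop("invalid config field 'family_strength': must be in [0, 1]")
  if (!is.list(target_spec) ||
      !all(vapply(target_spec, function(s) is.numeric(s) && length(s) %in% c(3L, 4L),
                  logical(1))))
    stop("invalid config field 'target_spec': list of c(n_edges, effect, confound_weight[, noise_sd])")
  structure(list(
    n_subjects = as.integer(n_subjects), n_parcels = as.integer(n_parcels),
    n_timepoints = as.integer(n_timepoints), n_runs = as.integer(n_runs),
    tr = tr, subject_snr = subject_snr, event_rate = event_rate,
    event_amplitude = event_amplitude, event_duration = as.integer(event_duration),
    noise_sd = noise_sd, n_families = as.integer(n_families),
    family_strength = family_strength, rss_fd_coupling = rss_fd_coupling,
    target_spec = target_spec, seed = as.integer(seed)), class = "cohort_config")
}

# random correlation matrix of rank-k + ridge structure
random_corr <- function(p, k = max(2L, ceiling(p / 4))) {
  W <- matrix(stats::rnorm(p * k), p, k)
  stats::cov2cor(tcrossprod(W) + 0.5 * k * diag(p))
}

# per-run multiplicative event-gain trace: 1 outside bursts,
# 1 + amplitude inside Poisson-placed bursts of `duration` frames
make_gain <- function(n_t, rate, amplitude, duration) {
  g <- rep(1, n_t)
  n_ev <- stats::rpois(1L, rate)
  if (n_ev > 0 && amplitude > 0) {
    starts <- sample.int(n_t, n_ev, replace = TRUE)
    for (s in starts) g[s:min(n_t, s + duration - 1L)] <- 1 + amplitude
  }
  g
}

# AR(1) positive motion trace (framewise displacement, mm)
make_fd <- function(n_t, mu = 0.12, phi = 0.6, innov_sd = 0.05) {
  e <- stats::rnorm(n_t, 0, innov_sd)
  fd <- numeric(n_t)
  fd[1] <- mu + e[1]
  for (t in 2:n_t) fd[t] <- mu + phi * (fd[t - 1] - mu) + e[t]
  pmax(fd, 0)
}

#' Generate a synthetic multi-subject BOLD cohort
#'
#' Draws every run as `x(t) = g(t) * L_s u(t) + noise`, where `L_s` is the
#' Cholesky factor of the subject's true covariance (population correlation
#' blended with family- and subject-level perturbations weighted by
#' `subject_snr`), `u(t)` are unit-variance Gaussian innovations and `g(t)`
#' is the event-gain trace. Phenotypes, confounds, per-run framewise
#' displacement, family labels and subject structural connectivity (SC,
#' streamline counts Poisson-distributed around a profile proportional to
#' the population FC) are generated alongside, and the ground truth needed
#' to verify recovery (subject covariances, gain traces, target
#' coefficients) is returned in `$truth`.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort` with fields `runs` (named list
#'   of [parcellated_run()], keys `<subject>_d<day>_<encoding>`),
#'   `phenotypes` (data.frame subject x target), `confounds` (data.frame
#'   with age, sex, fd_mean), `fd` (named list of per-run FD traces),
#'   `families` (named integer vector), `sc` (named list of [sc_matrix()]),
#'   `truth`, and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    p <- config$n_parcels
    n <- config$n_subjects
    n_t <- config$n_timepoints
    subjects <- sprintf("s%02d", seq_len(n))
    families <- stats::setNames(rep(seq_len(config$n_families), length.out = n), subjects)

    sigma_pop <- random_corr(p)
    fam_pert <- lapply(seq_len(config$n_families), function(f) random_corr(p))
    truth_sigma <- vector("list", n); names(truth_sigma) <- subjects
    chol_l <- vector("list", n)
    for (s in seq_len(n)) {
      d_s <- config$family_strength * fam_pert[[families[s]]] +
        (1 - config$family_strength) * random_corr(p)
      sigma_s <- stats::cov2cor((sigma_pop + config$subject_snr * d_s) /
                                  (1 + config$subject_snr))
      truth_sigma[[s]] <- sigma_s
      chol_l[[s]] <- t(chol(sigma_s + 1e-10 * diag(p)))
    }

    encodings <- if (config$n_runs == 4L) c("A", "B") else "A"
    runs <- list(); fd <- list(); gain <- list()
    for (s in seq_len(n)) {
      for (day in 1:2) {
        for (enc in encodings) {
          key <- sprintf("%s_d%d_%s", subjects[s], day, enc)
          g <- make_gain(n_t, config$event_rate, config$event_amplitude,
                         config$event_duration)
          u <- matrix(stats::rnorm(n_t * p), n_t, p)
          x <- (u %*% t(chol_l[[s]])) * g
          if (config$noise_sd > 0)
            x <- x + matrix(stats::rnorm(n_t * p, 0, config$noise_sd), n_t, p)
          runs[[key]] <- parcellated_run(x, tr = config$tr,
                                         subject_id = subjects[s],
                                         day = day, encoding = enc)
          f <- make_fd(n_t)
          if (config$rss_fd_coupling != 0)
            f <- pmax(f + config$rss_fd_coupling * 0.1 * (g - 1), 0)
          fd[[key]] <- f
          gain[[key]] <- g
        }
      }
    }

    age <- sample(22:37, n, replace = TRUE)
    sex <- stats::rbinom(n, 1L, 0.5)
    fd_mean <- vapply(subjects, function(sb) {
      mean(unlist(fd[grep(paste0("^", sb, "_"), names(fd))]))
    }, numeric(1))
    confounds <- data.frame(subject = subjects, age = age, sex = sex,
                            fd_mean = as.numeric(fd_mean))

    std0 <- function(v) {                       # centre/scale, 0 if constant
      s <- stats::sd(v)
      if (!is.finite(s) || s < 1e-12) return(rep(0, length(v)))
      (v - mean(v)) / s
    }
    conf_mix <- std0(std0(age) + std0(fd_mean) + 0.5 * std0(sex))
    n_edges <- p * (p - 1) / 2
    true_vecs <- t(vapply(truth_sigma, upper_vec, numeric(n_edges)))
    phenotypes <- data.frame(subject = subjects)
    truth_targets <- list()
    for (k in seq_along(config$target_spec)) {
      spec <- config$target_spec[[k]]
      n_inf <- as.integer(spec[1]); eff <- spec[2]; cw <- spec[3]
      tn <- if (length(spec) >= 4) spec[4] else 1
      edges <- sort(sample.int(n_edges, min(n_inf, n_edges)))
      w <- stats::rnorm(length(edges))
      sig <- std0(as.numeric(true_vecs[, edges, drop = FALSE] %*% w))
      y <- eff * sig + cw * conf_mix + stats::rnorm(n, 0, tn)
      nm <- sprintf("target_%d", k)
      phenotypes[[nm]] <- y
      truth_targets[[nm]] <- list(edges = edges, weights = w, effect_size = eff,
                                  confound_weight = cw, noise_sd = tn)
    }

    pop_vec <- upper_vec(sigma_pop)
    lam <- 20 + 180 * (pop_vec - min(pop_vec)) / (max(pop_vec) - min(pop_vec))
    sc <- lapply(subjects, function(sb) {
      m <- exp(stats::rnorm(1, 0, 0.1))
      sc_matrix(unvec_sym(stats::rpois(n_edges, lam * m), diag_value = 0))
    })
    names(sc) <- subjects

    structure(list(
      runs = runs, phenotypes = phenotypes, confounds = confounds, fd = fd,
      families = families, sc = sc,
      truth = list(sigma_pop = sigma_pop, sigma = truth_sigma, gain = gain,
                   targets = truth_targets),
      config = config), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects x %d runs, %d parcels, %d time points, %d families\n",
              x$config$n_subjects, x$config$n_runs, x$config$n_parcels,
              x$config$n_timepoints, x$config$n_families))
  invisible(x)
}

#' Subject identifiers of a cohort
#' @param cohort a `synthetic_cohort`.
#' @return character vector of subject ids in cohort order.
#' @export
cohort_subjects <- function(cohort) cohort$phenotypes$subject

#' Built-in reference cohorts
#'
#' `"tiny"` is the small fixed-seed cohort used throughout the test-suite
#' and the example pipeline: 6 subjects x 10 parcels x 120 time points x 4
#' runs, 3 families, one phenotype. `"worked"` is the hand-computable
#' 2-parcel, 3-frame pair of runs whose edge time series and FC can be
#' verified with pencil and paper.
#'
#' @param name one of `"tiny"`, `"worked"`.
#' @return a `synthetic_cohort`.
#' @export
make_fixture <- function(name = c("tiny", "worked")) {
  name <- match.arg(name)
  if (name == "tiny") {
    return(generate_cohort(cohort_config(
      n_subjects = 6, n_parcels = 10, n_timepoints = 120, n_runs = 4,
      tr = 0.72, subject_snr = 3, event_rate = 2, event_amplitude = 1,
      noise_sd = 0.3, n_families = 3, target_spec = list(c(8, 1, 0.3)),
      seed = 42L)))
  }
  # worked: x = (1,2,3), y = (3,2,1): population z-scores (-/+ 1.2247..., 0),
  # ETS = (-1.5, 0, -1.5), time-mean = -1 = Pearson r
  r1 <- parcellated_run(cbind(c(1, 2, 3), c(3, 2, 1)), tr = 1,
                        subject_id = "w01", day = 1, encoding = "A")
  r2 <- parcellated_run(cbind(c(1, 2, 3), c(1, 2, 3)), tr = 1,
                        subject_id = "w01", day = 2, encoding = "A")
  structure(list(
    runs = list(w01_d1_A = r1, w01_d2_A = r2),
    phenotypes = data.frame(subject = "w01"),
    confounds = data.frame(subject = "w01", age = 30, sex = 0, fd_mean = 0.1),
    fd = list(w01_d1_A = c(0.1, 0.1, 0.1), w01_d2_A = c(0.1, 0.1, 0.1)),
    families = c(w01 = 1L), sc = NULL, truth = NULL,
    config = NULL), class = "synthetic_cohort")
}
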