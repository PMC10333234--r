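make_confounds <- function(n_t = 40, seed = 1, fd = NULL) {
  set.seed(seed)
  confound_set(wm = rnorm(n_t), csf = rnorm(n_t), gs = rnorm(n_t),
               fd = fd %||% rep(0.1, n_t))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the WM/CSF/GS recipe yields 12 labelled columns plus spikes", {
  d <- build_confound_design(make_confounds())
  expect_equal(ncol(d), 12)
  expect_setequal(colnames(d),
                  as.vector(outer(c("wm", "csf", "gs"),
                                  c("", "_sq", "_dt", "_dt_sq"), paste0)))
  # spike rule: one one-hot column per supra-threshold frame
  cs <- make_confounds(n_t = 4, fd = c(0.1, 0.3, 0.1, 0.4))
  d2 <- build_confound_design(cs)
  expect_equal(ncol(d2), 14)
  sp <- d2[, c("spike_2", "spike_4")]
  expect_equal(colSums(sp), c(spike_2 = 1, spike_4 = 1))
  expect_equal(which(sp[, 1] == 1), 2)
  expect_equal(which(sp[, 2] == 1), 4)
  # column count is always 12 + number of supra-threshold frames
  for (seed in 1:3) {
    set.seed(seed)
    fd <- runif(30, 0, 0.5)
    di <- build_confound_design(make_confounds(30, seed, fd = fd))
    expect_equal(ncol(di), 12 + sum(fd > 0.25))
  }
})

test_that("a constant nuisance series has an all-zero derivative column", {
  cs <- confound_set(wm = rep(2, 20), csf = rnorm(20), gs = rnorm(20),
                     fd = rep(0, 20))
  d <- build_confound_design(cs)
  expect_equal(unname(d[, "wm_dt"]), rep(0, 20))
  expect_equal(unname(d[, "wm_dt_sq"]), rep(0, 20))
})

test_that("confound series must match the run length", {
  expect_error(confound_set(wm = rnorm(10), csf = rnorm(9), gs = rnorm(10),
                            fd = rep(0, 10)), "length")
  run <- rand_run(20, 3)
  expect_error(clean_run(run, design = matrix(0, 10, 1)), "10 rows")
})

test_that("regression removes design components; residuals are orthogonal", {
  set.seed(4)
  n_t <- 60
  conf <- rnorm(n_t)
  run <- parcellated_run(cbind(conf, rnorm(n_t), rnorm(n_t)), tr = 0.72)
  design <- cbind(wm = conf)
  out <- clean_run(run, design = design, band = NULL, detrend = FALSE)
  # a parcel equal to a design column is annihilated
  expect_lt(var(out$data[, 1]), 1e-10 * var(run$data[, 1]))
  # all output parcels orthogonal to every design column
  for (k in 2:3)
    expect_lt(abs(ref_pearson(out$data[, k], conf)), 1e-8)
})

test_that("out-of-band power is suppressed by at least 90 percent", {
  tr <- 0.72
  t_sec <- (0:599) * tr
  x <- sin(2 * pi * 0.2 * t_sec) + 0.5 * sin(2 * pi * 0.03 * t_sec)
  run <- parcellated_run(cbind(x, rnorm(600)), tr = tr)
  out <- clean_run(run, band = c(0.008, 0.08), detrend = FALSE)
  pow_at <- function(v, f) {
    pg <- spec.pgram(ts(v, frequency = 1 / tr), plot = FALSE, taper = 0)
    pg$spec[which.min(abs(pg$freq - f))]
  }
  # frequency-response oracle computed numerically from the periodogram
  expect_lt(pow_at(out$data[, 1], 0.2), 0.1 * pow_at(run$data[, 1], 0.2))
  # the in-band component survives
  expect_gt(pow_at(out$data[, 1], 0.03), 0.5 * pow_at(run$data[, 1], 0.03))
})

test_that("detrending removes a linear ramp", {
  run <- parcellated_run(cbind(seq_len(50), rnorm(50)), tr = 1)
  out <- clean_run(run, band = NULL, detrend = TRUE)
  slope <- coef(lm(out$data[, 1] ~ seq_len(50)))[2]
  expect_lt(abs(slope), 1e-10)
})

test_that("infeasible bands and rank-deficient designs are handled", {
  run <- rand_run(40, 3, tr = 10)      # Nyquist 0.05 Hz
  expect_error(clean_run(run, band = c(0.008, 0.08)), "infeasible")
  conf <- rnorm(40)
  d <- cbind(a = conf, b = 2 * conf)
  run2 <- rand_run(40, 3)
  expect_warning(out <- clean_run(run2, design = d, band = NULL),
                 "collinear")
  expect_lt(abs(ref_pearson(out$data[, 1], conf)), 1e-8)
})

test_that("run trimming obeys the head/tail arithmetic", {
  run <- rand_run(478, 4)
  expect_equal(trim_run(run, 20, 18)$n_timepoints, 440)
  expect_equal(trim_run(run, 0, 0)$data, run$data)
  expect_error(trim_run(rand_run(10, 2), 6, 5), "trim")
  # trimming composes additively
  a <- trim_run(trim_run(run, 5, 3), 15, 15)
  b <- trim_run(run, 20, 18)
  expect_equal(a$data, b$data)
})

test_that("RSS-motion correlation behaves as a Pearson diagnostic", {
  set.seed(9)
  rss <- abs(rnorm(60)) + 1
  expect_equal(rss_motion_correlation(rss, rss), 1)
  expect_equal(rss_motion_correlation(rss, -rss), -1)
  expect_error(rss_motion_correlation(rss, rep(1, 60)), "variance")
  expect_error(rss_motion_correlation(rss, rnorm(59)), "length")
})

test_that("RSS-FD correlations centre on zero when motion is uncoupled", {
  cfg <- cohort_config(n_subjects = 60, n_parcels = 10, n_timepoints = 120,
                       event_rate = 2, event_amplitude = 1, seed = 31)
  co <- generate_cohort(cfg)      # 240 runs, no induced coupling
  rs <- vapply(names(co$runs), function(key) {
    rss <- compute_rss(compute_ets(co$runs[[key]]))
    rss_motion_correlation(rss, co$fd[[key]])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.02)
  # with induced coupling the diagnostic must detect the shift
  cfg2 <- cohort_config(n_subjects = 20, n_parcels = 10, n_timepoints = 120,
                        event_rate = 4, event_amplitude = 2,
                        rss_fd_coupling = 5, seed = 32)
  co2 <- generate_cohort(cfg2)
  rs2 <- vapply(names(co2$runs), function(key) {
    rss <- compute_rss(compute_ets(co2$runs[[key]]))
    rss_motion_correlation(rss, co2$fd[[key]])
  }, numeric(1))
  expect_gt(mean(rs2), 0.1)
})
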