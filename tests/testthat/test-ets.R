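test_that("edge time series of the worked 2-parcel runs match hand values", {
  w <- make_fixture("worked")
  anti <- compute_ets(w$runs$w01_d1_A)       # x = (1,2,3), y = (3,2,1)
  expect_equal(as.numeric(anti$values), c(-1.5, 0, -1.5))
  expect_equal(mean(anti$values), -1)        # = Pearson r(x, y)
  same <- compute_ets(w$runs$w01_d2_A)       # y = x
  expect_equal(as.numeric(same$values), c(1.5, 0, 1.5))
  expect_equal(mean(same$values), 1)
})

test_that("the ETS time-mean equals full-run Pearson FC edge-for-edge", {
  for (seed in 1:4) {
    run <- rand_run(50, 6, seed = seed)
    ets <- compute_ets(run)
    # independent oracle: plain Pearson per edge
    idx <- ets$edge_index
    oracle <- vapply(seq_len(nrow(idx)), function(e)
      ref_pearson(run$data[, idx$i[e]], run$data[, idx$j[e]]), numeric(1))
    expect_lt(max(abs(colMeans(ets$values) - oracle)), 1e-12)
  }
})

test_that("zero-variance parcels are reported by index", {
  run <- parcellated_run(cbind(rnorm(20), rep(3, 20)), tr = 1)
  expect_error(compute_ets(run), "2")
})

test_that("RSS is the per-frame root sum of squares of the ETS", {
  ets <- structure(list(values = rbind(c(3, 4), c(0, 0)),
                        edge_index = edge_index(2), run_key = "x"),
                   class = "edge_time_series")
  expect_equal(compute_rss(ets)$values, c(5, 0))
  run <- rand_run(30, 5, seed = 2)
  e <- compute_ets(run)
  # independent accumulation loop
  oracle <- vapply(seq_len(30), function(t) {
    acc <- 0
    for (v in e$values[t, ]) acc <- acc + v^2
    sqrt(acc)
  }, numeric(1))
  expect_lt(max(abs(compute_rss(e)$values - oracle)), 1e-12)
})

test_that("RSS is invariant to parcel reordering", {
  run <- rand_run(40, 6, seed = 5)
  perm <- c(4, 1, 6, 2, 5, 3)
  run2 <- parcellated_run(run$data[, perm], tr = run$tr)
  expect_equal(compute_rss(compute_ets(run))$values,
               compute_rss(compute_ets(run2))$values)
})

test_that("frames rank by descending RSS with stable tie-breaking", {
  expect_equal(rank_time_points(c(0.5, 2.0, 1.0)), c(2, 3, 1))
  expect_equal(rank_time_points(c(1.0, 1.0)), c(1, 2))
  set.seed(8)
  v <- runif(100)
  expect_equal(rank_time_points(v), order(v, decreasing = TRUE))
})

test_that("bin selection reproduces the printed bin arithmetic", {
  rk <- seq_len(1200)
  expect_length(select_time_points(rk, sampling_spec("individual_bin",
                                                     bin = 1, n_bins = 20)), 60)
  rk8 <- seq_len(440)
  for (b in c(1, 4, 8))
    expect_length(select_time_points(rk8, sampling_spec("individual_bin",
                                                        bin = b, n_bins = 8)), 55)
  comb <- select_time_points(rk, sampling_spec("combined_bins",
                                               bin_pair = c(1, 20), n_bins = 20))
  expect_length(comb, 120)
  b1 <- select_time_points(rk, sampling_spec("individual_bin", bin = 1, n_bins = 20))
  b20 <- select_time_points(rk, sampling_spec("individual_bin", bin = 20, n_bins = 20))
  expect_length(intersect(b1, b20), 0)
  expect_setequal(comb, union(b1, b20))
  expect_length(select_time_points(rk, sampling_spec("full")), 1200)
})

test_that("individual bins partition the frames", {
  set.seed(3)
  rk <- rank_time_points(runif(120))
  bins <- lapply(1:20, function(b)
    select_time_points(rk, sampling_spec("individual_bin", bin = b, n_bins = 20)))
  expect_setequal(unlist(bins), 1:120)
  expect_equal(sum(lengths(bins)), 120)
})

test_that("sequential thresholds complement each other and recover full FC", {
  set.seed(4)
  rk <- rank_time_points(runif(200))
  h <- select_time_points(rk, sampling_spec("sequential_hacf", threshold_pct = 30))
  l <- select_time_points(rk, sampling_spec("sequential_lacf", threshold_pct = 70))
  expect_setequal(c(h, l), 1:200)
  full <- select_time_points(rk, sampling_spec("sequential_hacf", threshold_pct = 100))
  expect_equal(full, 1:200)
  run <- rand_run(200, 5, seed = 4)
  expect_equal(sampled_fc(run, sampling_spec("sequential_hacf",
                                             threshold_pct = 100))$matrix,
               estimate_fc(run)$matrix)
})

test_that("invalid sampling requests fail loudly", {
  rk <- seq_len(100)
  expect_error(select_time_points(rk, sampling_spec("individual_bin",
                                                    bin = 2, n_bins = 7)),
               "divided")
  expect_error(select_time_points(rk, sampling_spec("sequential_hacf",
                                                    threshold_pct = 1)),
               "< 2")
  expect_error(sampling_spec("individual_bin", bin = 21, n_bins = 20))
  expect_error(sampling_spec("combined_bins", bin_pair = c(3, 3)))
  expect_error(sampling_spec("sequential_hacf", threshold_pct = 0))
})

test_that("subset FC equals brute-force Pearson on the extracted frames", {
  run <- rand_run(100, 6, seed = 6)
  set.seed(7)
  idx <- sort(sample(100, 40))
  fc <- estimate_fc(run, idx)
  sub <- run$data[idx, ]
  ei <- edge_index(6)
  for (e in seq_len(nrow(ei)))
    expect_equal(fc$vec[e], ref_pearson(sub[, ei$i[e]], sub[, ei$j[e]]),
                 tolerance = 1e-12)
  expect_equal(fc$matrix, t(fc$matrix))
  expect_equal(diag(fc$matrix), rep(1, 6))
  # indices = all frames gives the full-run FC
  expect_equal(estimate_fc(run, 1:100)$matrix, estimate_fc(run)$matrix)
  # proportional parcels on the subset
  d <- matrix(rnorm(60), 30, 2); d[, 2] <- 2 * d[, 1]
  expect_equal(estimate_fc(parcellated_run(d, tr = 1))$matrix[1, 2], 1)
})

test_that("a parcel constant over the subset gets zero correlations", {
  d <- cbind(c(rep(1, 5), rnorm(15)), rnorm(20), rnorm(20))
  run <- parcellated_run(d, tr = 1)
  expect_warning(fc <- estimate_fc(run, 1:5), "constant")
  expect_equal(fc$matrix[1, 2], 0)
  expect_equal(fc$matrix[1, 3], 0)
  expect_equal(diag(fc$matrix), rep(1, 3))
})

test_that("FC averaging respects the aggregation level", {
  co <- make_fixture("tiny")
  fcs <- lapply(names(co$runs), function(k) estimate_fc(co$runs[[k]]))
  per_day <- aggregate_fc(fcs, "per_day")
  per_subj <- aggregate_fc(fcs, "per_subject")
  expect_length(per_day, 12)     # 6 subjects x 2 days
  expect_length(per_subj, 6)
  # element-wise mean oracle for one subject-day
  keys <- grep("^s01_d1", names(co$runs), value = TRUE)
  oracle <- (estimate_fc(co$runs[[keys[1]]])$matrix +
             estimate_fc(co$runs[[keys[2]]])$matrix) / 2
  expect_equal(per_day$s01_d1$matrix, oracle)
  # averaging identical matrices is the identity; A and -A cancel off-diagonal
  m <- estimate_fc(co$runs[[1]])$matrix
  f1 <- fc_matrix(m, provenance = list(subject = "a", day = 1))
  expect_equal(aggregate_fc(list(f1, f1), "per_day")$a_d1$matrix, m)
  neg <- -m; diag(neg) <- 1
  f2 <- fc_matrix(neg, provenance = list(subject = "a", day = 1))
  avg <- aggregate_fc(list(f1, f2), "per_day")$a_d1$matrix
  expect_equal(avg[upper.tri(avg)], rep(0, sum(upper.tri(avg))))
})
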