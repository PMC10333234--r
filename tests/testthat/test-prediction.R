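test_that("confound removal fits on train only and matches normal equations", {
  set.seed(1)
  n <- 40
  conf_tr <- cbind(age = rnorm(n), fd = rnorm(n))
  conf_te <- cbind(age = rnorm(10), fd = rnorm(10))
  # target exactly linear in confounds: train residuals vanish
  y_tr <- 2 + 0.5 * conf_tr[, 1] - 1.5 * conf_tr[, 2]
  y_te <- 2 + 0.5 * conf_te[, 1] - 1.5 * conf_te[, 2]
  rt <- residualize_targets(y_tr, conf_tr, y_te, conf_te)
  expect_lt(max(abs(rt$train)), 1e-10)
  expect_lt(max(abs(rt$test)), 1e-10)
  # centred target orthogonal to a centred confound is untouched
  x <- scale(rnorm(n), scale = FALSE)[, 1]
  y <- scale(rnorm(n), scale = FALSE)[, 1]
  y <- y - x * sum(x * y) / sum(x^2)
  rt2 <- residualize_targets(y, cbind(c = x), y, cbind(c = x))
  expect_lt(max(abs(rt2$train - y)), 1e-10)
  # closed-form normal-equations oracle
  set.seed(2)
  yy <- rnorm(n); cc <- cbind(a = rnorm(n), b = rnorm(n))
  rt3 <- residualize_targets(yy, cc, yy[1:5], cc[1:5, ])
  X <- cbind(1, cc)
  beta <- solve(t(X) %*% X, t(X) %*% yy)
  expect_equal(unname(rt3$model$coefficients), as.numeric(beta),
               tolerance = 1e-10)
  # collinear confounds are dropped with a warning
  expect_warning(residualize_targets(yy, cbind(a = cc[, 1], b = 2 * cc[, 1]),
                                     yy, cbind(a = cc[, 1], b = 2 * cc[, 1])),
                 "rank-deficient")
})

test_that("the Pearson kernel is the correlation-similarity Gram matrix", {
  set.seed(3)
  A <- matrix(rnorm(50), 5, 10)
  K <- pearson_kernel(A)
  expect_equal(diag(K), rep(1, 5))
  for (a in 1:5) for (b in 1:5)
    expect_equal(K[a, b], ref_pearson(A[a, ], A[b, ]), tolerance = 1e-12)
  B <- rbind(A[1, ] * 3 + 2)           # positive affine rescale of row 1
  expect_equal(pearson_kernel(B, A)[1, 1], 1)
  expect_error(pearson_kernel(rbind(rep(1, 10))), "constant")
})

test_that("kernel ridge interpolates at alpha 0 and shrinks to the mean", {
  set.seed(4)
  A <- matrix(rnorm(80), 8, 10)
  K <- pearson_kernel(A)
  y <- rnorm(8)
  m0 <- kernel_ridge(K, y, 0)
  expect_lt(max(abs(predict_kernel_ridge(m0, K) - y)), 1e-8)
  mbig <- kernel_ridge(K, y, 1e12)
  expect_lt(max(abs(predict_kernel_ridge(mbig, K) - mean(y))), 1e-6)
  # direct linear-solve oracle
  alpha <- 2.5
  mfit <- kernel_ridge(K, y, alpha)
  oracle <- solve(K + alpha * diag(8)) %*% (y - mean(y))
  expect_equal(mfit$dual, as.numeric(oracle), tolerance = 1e-8)
  expect_error(kernel_ridge(K, y, -1), "nonnegative")
})

test_that("scoring metrics implement their printed definitions", {
  expect_equal(score(c(1, 2, 3), c(1, 2, 3), "pearson_r"), 1)
  expect_equal(score(c(1, 2, 3), c(1, 2, 3), "r2"), 1)
  expect_equal(score(c(1, 2, 3), c(1, 2, 3), "mae"), 0)
  y <- c(1, 2, 3, 10)
  expect_equal(score(y, rep(mean(y), 4), "r2"), 0)
  # textbook covariance-based oracle for Pearson r
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(score(a, b, "pearson_r"), ref_pearson(a, b), tolerance = 1e-12)
  expect_equal(score(a, b, "mae"), mean(abs(a - b)))
  # confusion arithmetic: TP=50, FN=0, TN=25, FP=25
  yl <- c(rep(1, 50), rep(0, 50))
  yh <- c(rep(1, 50), rep(1, 25), rep(0, 25))
  expect_equal(score(yl, yh, "accuracy"), 0.75)
  expect_equal(score(yl, yh, "balanced_accuracy"), (1 + 0.5) / 2)
  # balanced accuracy equals plain accuracy under balanced classes
  set.seed(6)
  yt <- rep(c(0, 1), each = 30)
  yp <- sample(c(0, 1), 60, replace = TRUE)
  expect_equal(score(yt, yp, "balanced_accuracy"),
               score(yt, yp, "accuracy"), tolerance = 1e-12)
})

test_that("the default regularisation grid matches the printed candidates", {
  expect_equal(default_alpha_grid(),
               c(0, 0.00001, 0.0001, 0.001, 0.004, 0.007, 0.01, 0.04, 0.07,
                 0.1, 0.4, 0.7, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 10, 15, 20, 30,
                 40, 50, 60, 70, 80, 100, 150, 200, 300, 500, 700, 1000,
                 10000, 100000, 1000000))
  cg <- default_c_grid()
  expect_length(cg, 50)
  expect_equal(cg[1], 0.01)
  expect_equal(cg[50], 100)
  expect_equal(diff(log(cg)), rep(diff(log(c(0.01, 100))) / 49, 49))
})

test_that("grouped folds never split a family", {
  set.seed(7)
  groups <- sample(1:12, 60, replace = TRUE)
  for (seed in 1:5) {
    folds <- make_folds(60, 5, groups = groups, seed = seed)
    expect_setequal(unique(folds), 1:5)
    for (g in unique(groups))
      expect_length(unique(folds[groups == g]), 1)
  }
  plain <- make_folds(20, 4, seed = 1)
  expect_equal(sort(table(plain)), sort(table(rep(1:4, 5))), ignore_attr = TRUE)
  expect_error(make_folds(10, 11), "folds")
  expect_error(make_folds(10, 6, groups = rep(1:3, length.out = 10)), "groups")
})

test_that("CBPM selects informative edges and predicts from network sums", {
  set.seed(8)
  n <- 60
  X <- matrix(rnorm(n * 40), n, 40)
  y <- 2 * X[, 7]                     # single perfectly informative edge
  # a stringent screen keeps chance edges out of the unweighted network sums
  fit <- cbpm(X[1:40, ], y[1:40], X[41:60, ], p_threshold = 1e-8)
  expect_equal(fit$positive_edges, 7L, ignore_attr = TRUE)
  expect_gt(ref_pearson(fit$predictions, y[41:60]), 0.99)
  # p_threshold = 1 selects every edge
  all_fit <- cbpm(X[1:40, ], y[1:40], X[41:60, ], p_threshold = 1)
  expect_equal(sort(c(all_fit$positive_edges, all_fit$negative_edges)), 1:40)
  # intercept-only fallback when nothing passes
  yn <- rnorm(40)
  none <- cbpm(X[1:40, ], yn, X[41:60, ], p_threshold = 1e-12)
  expect_true(none$fallback)
  expect_equal(none$predictions, rep(mean(yn), 20))
})

test_that("CBPM edge screening has the nominal type-I rate", {
  set.seed(9)
  frac <- replicate(30, {
    X <- matrix(rnorm(50 * 200), 50, 200)
    y <- rnorm(50)
    fit <- cbpm(X, y, X[1:3, ], p_threshold = 0.01)
    (length(fit$positive_edges) + length(fit$negative_edges)) / 200
  })
  expect_lt(abs(mean(frac) - 0.01), 0.01)
})

test_that("nested CV predicts a separable binary label with the ridge classifier", {
  set.seed(10)
  n <- 80
  X <- matrix(rnorm(n * 30), n, 30)
  y <- as.integer(X[, 1] + X[, 2] + 0.2 * rnorm(n) > 0)
  cv <- cv_spec("repeated_kfold", k_outer = 5, seed = 2)
  pr <- run_prediction_cv(X, y, cv = cv, model = "ridge_classifier",
                          grid = c(0.1, 1, 10))
  expect_gt(pr$mean_scores[["accuracy"]], 0.7)
  expect_true(all(pr$scores$accuracy >= 0 & pr$scores$accuracy <= 1))
  expect_equal(nrow(pr$scores), 5)
})

test_that("repeated k-fold produces one score row per repeat and fold", {
  set.seed(11)
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- rnorm(40)
  cv <- cv_spec("repeated_kfold", k_outer = 4, n_repeats = 3, seed = 1)
  pr <- run_prediction_cv(X, y, cv = cv, grid = c(1, 10))
  expect_equal(nrow(pr$scores), 12)
  expect_setequal(unique(pr$scores$rep), 1:3)
  expect_true(all(pr$chosen$hyperparameter %in% c(1, 10)))
  # determinism under the cv seed
  pr2 <- run_prediction_cv(X, y, cv = cv, grid = c(1, 10))
  expect_equal(pr$scores, pr2$scores)
})
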