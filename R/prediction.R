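#' Candidate l2-regularisation strengths for ridge models
#'
#' The default hyperparameter grid searched by the inner cross-validation
#' for kernel ridge regression and the ridge classifier.
#'
#' @return numeric vector of 39 candidate values from 0 to 1e6.
#' @export
default_alpha_grid <- function() {
  c(0, 0.00001, 0.0001, 0.001, 0.004, 0.007, 0.01, 0.04, 0.07, 0.1, 0.4,
    0.7, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 10, 15, 20, 30, 40, 50, 60, 70, 80,
    100, 150, 200, 300, 500, 700, 1000, 10000, 100000, 1000000)
}

#' Candidate C values for margin classifiers
#'
#' 50 values log-spaced between 0.01 and 100; kept for completeness of the
#' configuration surface (support-vector robustness checks are out of this
#' package's scope).
#'
#' @return numeric vector of length 50.
#' @export
default_c_grid <- function() {
  exp(seq(log(0.01), log(100), length.out = 50))
}

#' Cross-validation specification
#'
#' `grouped_kfold` is a single k-fold split in which all members of a
#' family land in the same fold (fold independence under family
#' structure); `repeated_kfold` is plain k-fold repeated `n_repeats`
#' times. Hyperparameters are always selected by a `k_inner`-fold inner
#' loop on the training folds.
#'
#' @param scheme `"grouped_kfold"` or `"repeated_kfold"`.
#' @param k_outer number of outer folds (10 for the grouped scheme, 5 for
#'   the repeated scheme, typically).
#' @param n_repeats repeats of the outer split (repeated scheme only).
#' @param k_inner inner folds for hyperparameter selection.
#' @param groups subject-to-family assignment (vector aligned with the
#'   feature rows); required for the grouped scheme.
#' @param seed RNG seed for fold assignment.
#' @return object of class `cv_spec`.
#' @export
cv_spec <- function(scheme = c("grouped_kfold", "repeated_kfold"),
                    k_outer = 10L, n_repeats = 1L, k_inner = 5L,
                    groups = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  if (k_outer < 2) stop("k_outer must be >= 2")
  if (scheme == "grouped_kfold" && is.null(groups))
    stop("grouped_kfold requires groups")
  if (scheme == "repeated_kfold") groups <- NULL else n_repeats <- 1L
  structure(list(scheme = scheme, k_outer = as.integer(k_outer),
                 n_repeats = as.integer(n_repeats), k_inner = as.integer(k_inner),
                 groups = groups, seed = as.integer(seed)), class = "cv_spec")
}

#' Assign rows to cross-validation folds
#'
#' Plain k-fold shuffles rows into balanced folds. With `groups`, whole
#' groups (families) are assigned greedily — largest group first, random
#' tie-breaking — to the currently smallest fold, so no group is ever
#' split across folds.
#'
#' @param n number of rows.
#' @param k number of folds.
#' @param groups optional group label per row.
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..k, length n.
#' @export
make_folds <- function(n, k, groups = NULL, seed = 1L) {
  with_seed(seed, {
    if (is.null(groups)) {
      if (k > n) stop("more folds than rows")
      return(sample(rep_len(seq_len(k), n)))
    }
    if (length(groups) != n) stop("groups must have length n")
    fams <- unique(groups)
    if (k > length(fams)) stop("more folds than groups")
    sizes <- table(factor(groups, levels = fams))
    ord <- fams[order(-as.integer(sizes), stats::runif(length(fams)))]
    fold_of_fam <- integer(length(fams)); names(fold_of_fam) <- fams
    load <- integer(k)
    for (f in ord) {
      tgt <- which.min(load)
      fold_of_fam[[as.character(f)]] <- tgt
      load[tgt] <- load[tgt] + sizes[[as.character(f)]]
    }
    unname(fold_of_fam[as.character(groups)])
  })
}

#' Cross-validation-consistent confound removal from targets
#'
#' Fits ordinary least squares of the target on the confounds (with
#' intercept) using the training partition only, and returns the residuals
#' of both partitions under the training coefficients — so no information
#' about test targets ever enters the confound model.
#'
#' @param train_targets,test_targets numeric target vectors.
#' @param train_confounds,test_confounds confound matrices/data.frames with
#'   matching columns.
#' @return list with `train`, `test` (residualised targets) and `model`
#'   (coefficients and the confound columns retained).
#' @export
residualize_targets <- function(train_targets, train_confounds,
                                test_targets, test_confounds) {
  x_tr <- cbind(intercept = 1, as.matrix(train_confounds))
  x_te <- cbind(intercept = 1, as.matrix(test_confounds))
  if (anyNA(x_tr) || anyNA(train_targets)) stop("missing values in training data")
  qx <- qr(x_tr)
  keep <- seq_len(ncol(x_tr))
  if (qx$rank < ncol(x_tr)) {
    drop <- qx$pivot[seq.int(qx$rank + 1L, ncol(x_tr))]
    warning("rank-deficient confounds; dropping column(s): ",
            paste(colnames(x_tr)[drop], collapse = ", "))
    keep <- setdiff(keep, drop)
    x_tr <- x_tr[, keep, drop = FALSE]
    x_te <- x_te[, keep, drop = FALSE]
  }
  beta <- qr.solve(x_tr, train_targets)
  list(train = as.numeric(train_targets - x_tr %*% beta),
       test = as.numeric(test_targets - x_te %*% beta),
       model = list(coefficients = stats::setNames(as.numeric(beta),
                                                   colnames(x_tr)),
                    columns = colnames(x_tr)))
}

# confound removal from a feature matrix (classification recipe): one OLS
# per feature column, solved jointly; returns residualised train and test
# feature blocks plus the coefficient matrix
residualize_features <- function(train_features, train_confounds,
                                 test_features, test_confounds) {
  x_tr <- cbind(intercept = 1, as.matrix(train_confounds))
  x_te <- cbind(intercept = 1, as.matrix(test_confounds))
  beta <- qr.solve(x_tr, train_features)
  list(train = train_features - x_tr %*% beta,
       test = test_features - x_te %*% beta,
       model = list(coefficients = beta))
}

#' Pearson similarity kernel
#'
#' K(a, b) is the Pearson correlation between row a of `A` and row b of
#' `B` — the correlation-similarity Gram matrix used as the kernel for
#' ridge regression on FC edge vectors.
#'
#' @param A,B subject x edge matrices with at least 2 columns and no
#'   constant rows.
#' @return `nrow(A)` x `nrow(B)` kernel matrix.
#' @export
pearson_kernel <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) < 2) stop("need at least 2 edges")
  if (any(apply(A, 1, stats::sd) == 0) || any(apply(B, 1, stats::sd) == 0))
    stop("constant feature row")
  stats::cor(t(A), t(B))
}

#' Kernel ridge regression
#'
#' Solves `(K + alpha I) c = y - mean(y)`; predictions are
#' `K_test c + mean(y)`. At `alpha = 0` a fixed jitter of 1e-10 is added to
#' keep the solve well posed.
#'
#' @param K_train square kernel matrix on the training subjects.
#' @param y_train training targets.
#' @param alpha l2-regularisation strength, >= 0.
#' @return object of class `kernel_ridge` with dual coefficients and
#'   intercept; predict with [predict_kernel_ridge()].
#' @export
kernel_ridge <- function(K_train, y_train, alpha) {
  if (alpha < 0) stop("alpha must be nonnegative")
  n <- nrow(K_train)
  jitter <- if (alpha == 0) 1e-10 else 0
  intercept <- mean(y_train)
  dual <- solve(K_train + (alpha + jitter) * diag(n), y_train - intercept)
  structure(list(dual = as.numeric(dual), intercept = intercept,
                 alpha = alpha), class = "kernel_ridge")
}

#' Predict from a kernel ridge fit
#'
#' @param model a [kernel_ridge()] fit.
#' @param K_test test x train kernel block.
#' @return numeric predictions.
#' @export
predict_kernel_ridge <- function(model, K_test) {
  as.numeric(K_test %*% model$dual + model$intercept)
}

#' Connectome-based predictive modelling
#'
#' Screens every edge by its Pearson correlation with the training target;
#' edges significant at `p_threshold` (two-tailed, unadjusted) are split by
#' correlation sign into a positive and a negative network, each summed per
#' subject, and a linear model of the target on the two network sums is fit
#' on the training subjects and applied to the test subjects. If no edge
#' passes the screen the model falls back to the intercept (train mean),
#' flagged in the result.
#'
#' @param train_features,test_features subject x edge matrices.
#' @param train_target training target vector.
#' @param p_threshold edge-selection significance threshold.
#' @return list with `predictions`, `positive_edges`, `negative_edges`,
#'   `coefficients`, `fallback`.
#' @export
cbpm <- function(train_features, train_target, test_features,
                 p_threshold = 0.01) {
  n <- nrow(train_features)
  if (n < 3) stop("need at least 3 training subjects")
  r <- suppressWarnings(as.numeric(stats::cor(train_features, train_target)))
  r[is.na(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pos <- which(p < p_threshold & r > 0)
  neg <- which(p < p_threshold & r < 0)
  sums <- function(x) {
    out <- NULL
    if (length(pos)) out <- cbind(out, pos_sum = rowSums(x[, pos, drop = FALSE]))
    if (length(neg)) out <- cbind(out, neg_sum = rowSums(x[, neg, drop = FALSE]))
    out
  }
  s_tr <- sums(train_features)
  if (is.null(s_tr)) {
    return(list(predictions = rep(mean(train_target), nrow(test_features)),
                positive_edges = integer(0), negative_edges = integer(0),
                coefficients = c(intercept = mean(train_target)),
                fallback = TRUE))
  }
  x_tr <- cbind(intercept = 1, s_tr)
  beta <- qr.solve(x_tr, train_target)
  x_te <- cbind(intercept = 1, sums(test_features))
  list(predictions = as.numeric(x_te %*% beta),
       positive_edges = pos, negative_edges = neg,
       coefficients = stats::setNames(as.numeric(beta), colnames(x_tr)),
       fallback = FALSE)
}

#' Prediction scoring metrics
#'
#' `pearson_r` is the product-moment correlation between observed and
#' predicted values; `r2` the coefficient of determination
#' 1 - SSE/SST; `mae` the mean absolute error; `accuracy` the fraction of
#' matching labels; `balanced_accuracy` the mean of sensitivity
#' TP/(TP+FN) and specificity TN/(TN+FP).
#'
#' @param y observed values (labels for classification metrics).
#' @param y_hat predicted values/labels.
#' @param metric one of `"pearson_r"`, `"r2"`, `"mae"`, `"accuracy"`,
#'   `"balanced_accuracy"`.
#' @return scalar score.
#' @export
score <- function(y, y_hat, metric = c("pearson_r", "r2", "mae",
                                       "accuracy", "balanced_accuracy")) {
  metric <- match.arg(metric)
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  switch(metric,
    pearson_r = pearson_r(y, y_hat),
    r2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2),
    mae = mean(abs(y - y_hat)),
    accuracy = mean(y == y_hat),
    balanced_accuracy = {
      cls <- sort(unique(y))
      if (length(cls) != 2) stop("balanced_accuracy needs exactly 2 classes in y")
      pos <- cls[2]; neg <- cls[1]
      tp <- sum(y == pos & y_hat == pos); fn <- sum(y == pos & y_hat != pos)
      tn <- sum(y == neg & y_hat == neg); fp <- sum(y == neg & y_hat != neg)
      0.5 * (tp / (tp + fn) + tn / (tn + fp))
    })
}

#' Nested cross-validated phenotype prediction
#'
#' Outer folds per the CV specification estimate generalisation; a
#' `k_inner`-fold loop on each training set selects the hyperparameter
#' maximising the inner validation score (Pearson r for regression,
#' accuracy for classification); the winning model is refit on the full
#' outer training set and scored on the held-out fold. Confounds are
#' handled CV-consistently inside every split: for regression they are
#' regressed from the targets (train-fitted model applied to test), for
#' classification from the features.
#'
#' Models: `kernel_ridge` (Pearson-kernel ridge regression, grid =
#' l2 strengths), `cbpm` (grid = edge-selection p thresholds),
#' `ridge_classifier` (Pearson-kernel ridge on +/-1 labels, sign decision,
#' grid = l2 strengths).
#'
#' @param features subject x edge matrix.
#' @param target phenotype vector (binary labels for the classifier).
#' @param confounds subject x confound matrix/data.frame, or `NULL`.
#' @param cv a [cv_spec()].
#' @param model `"kernel_ridge"`, `"cbpm"` or `"ridge_classifier"`.
#' @param grid hyperparameter candidates; defaults to
#'   [default_alpha_grid()] for ridge models and 0.01 for CBPM.
#' @param metrics score names (see [score()]); defaults to
#'   `c("pearson_r", "r2", "mae")` for regression, accuracy metrics for
#'   classification.
#' @return object of class `prediction_result`: `$scores` (one row per
#'   repeat x outer fold with every metric), `$chosen` (selected
#'   hyperparameter per fold), `$fold_details` (per-fold confound model
#'   and fitted coefficients, for leakage audits), `$mean_scores`.
#' @export
run_prediction_cv <- function(features, target, confounds = NULL,
                              cv = NULL,
                              model = c("kernel_ridge", "cbpm", "ridge_classifier"),
                              grid = NULL, metrics = NULL) {
  model <- match.arg(model)
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(target) != n) stop("target length must match feature rows")
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) stop("confound rows must match feature rows")
  }
  if (is.null(cv)) cv <- cv_spec("repeated_kfold", k_outer = 5L)
  classification <- model == "ridge_classifier"
  if (is.null(grid))
    grid <- if (model == "cbpm") 0.01 else default_alpha_grid()
  if (is.null(metrics))
    metrics <- if (classification) c("accuracy", "balanced_accuracy")
               else c("pearson_r", "r2", "mae")
  inner_metric <- if (classification) "accuracy" else "pearson_r"

  if (classification) {
    cls <- sort(unique(target))
    if (length(cls) != 2) stop("ridge_classifier needs a binary target")
    y_signed <- ifelse(target == cls[2], 1, -1)
  }

  # kernel reusable across folds whenever the features are not modified
  K_all <- if (model != "cbpm" && (!classification || is.null(confounds)))
    pearson_kernel(features) else NULL

  fit_score <- function(tr, te, hyper, want_details = FALSE) {
    # returns predictions on te (and observed values to score against)
    if (model == "cbpm") {
      rt <- if (!is.null(confounds))
        residualize_targets(target[tr], confounds[tr, , drop = FALSE],
                            target[te], confounds[te, , drop = FALSE])
      else list(train = target[tr], test = target[te], model = NULL)
      fit <- cbpm(features[tr, , drop = FALSE], rt$train,
                  features[te, , drop = FALSE], p_threshold = hyper)
      list(obs = rt$test, pred = fit$predictions,
           details = if (want_details)
             list(confound_model = rt$model, coefficients = fit$coefficients,
                  positive_edges = fit$positive_edges,
                  negative_edges = fit$negative_edges))
    } else if (!classification) {
      rt <- if (!is.null(confounds))
        residualize_targets(target[tr], confounds[tr, , drop = FALSE],
                            target[te], confounds[te, , drop = FALSE])
      else list(train = target[tr], test = target[te], model = NULL)
      fit <- kernel_ridge(K_all[tr, tr, drop = FALSE], rt$train, alpha = hyper)
      pred <- predict_kernel_ridge(fit, K_all[te, tr, drop = FALSE])
      list(obs = rt$test, pred = pred,
           details = if (want_details)
             list(confound_model = rt$model, dual = fit$dual,
                  intercept = fit$intercept))
    } else {
      if (!is.null(confounds)) {
        rf <- residualize_features(features[tr, , drop = FALSE],
                                   confounds[tr, , drop = FALSE],
                                   features[te, , drop = FALSE],
                                   confounds[te, , drop = FALSE])
        K_tr <- pearson_kernel(rf$train)
        K_te <- pearson_kernel(rf$test, rf$train)
        cm <- rf$model
      } else {
        K_tr <- K_all[tr, tr, drop = FALSE]
        K_te <- K_all[te, tr, drop = FALSE]
        cm <- NULL
      }
      fit <- kernel_ridge(K_tr, y_signed[tr], alpha = hyper)
      raw <- predict_kernel_ridge(fit, K_te)
      pred <- ifelse(raw >= 0, cls[2], cls[1])
      list(obs = target[te], pred = pred,
           details = if (want_details)
             list(confound_model = cm, dual = fit$dual,
                  intercept = fit$intercept))
    }
  }

  safe_score <- function(obs, pred, metric) {
    tryCatch(score(obs, pred, metric), error = function(e) NA_real_)
  }

  scores <- list(); chosen <- list(); fold_details <- list()
  for (rep_i in seq_len(cv$n_repeats)) {
    folds <- make_folds(n, cv$k_outer, groups = cv$groups,
                        seed = child_seed(cv$seed, rep_i))
    for (fold_i in seq_len(cv$k_outer)) {
      te <- which(folds == fold_i)
      tr <- which(folds != fold_i)
      if (length(te) < 2) stop("outer fold with fewer than 2 test subjects")
      # inner hyperparameter selection on the training set only; the inner
      # fold count is capped by what the training set can support
      best <- grid[1]
      k_in <- min(cv$k_inner,
                  if (!is.null(cv$groups)) length(unique(cv$groups[tr]))
                  else length(tr) %/% 2L)
      if (length(grid) > 1 && k_in >= 2) {
        inner <- make_folds(length(tr), k_in,
                            groups = if (!is.null(cv$groups)) cv$groups[tr],
                            seed = child_seed(cv$seed, 1000L * rep_i + fold_i))
        mean_sc <- vapply(grid, function(h) {
          sc <- vapply(seq_len(k_in), function(ii) {
            ite <- tr[inner == ii]; itr <- tr[inner != ii]
            if (length(ite) < 2) return(NA_real_)
            fs <- fit_score(itr, ite, h)
            safe_score(fs$obs, fs$pred, inner_metric)
          }, numeric(1))
          mean(sc, na.rm = TRUE)
        }, numeric(1))
        if (any(is.finite(mean_sc)))       # ties resolve to the smallest value
          best <- grid[which.max(mean_sc)]
      }
      fs <- fit_score(tr, te, best, want_details = TRUE)
      row <- c(list(rep = rep_i, fold = fold_i, hyperparameter = best),
               stats::setNames(lapply(metrics, function(m)
                 safe_score(fs$obs, fs$pred, m)), metrics))
      scores[[length(scores) + 1L]] <- as.data.frame(row)
      fold_details[[sprintf("rep%d_fold%d", rep_i, fold_i)]] <-
        c(fs$details, list(test_index = te))
    }
  }
  scores <- do.call(rbind, scores)
  structure(list(scores = scores,
                 chosen = scores[, c("rep", "fold", "hyperparameter")],
                 fold_details = fold_details,
                 mean_scores = colMeans(scores[, metrics, drop = FALSE],
                                        na.rm = TRUE),
                 model = model, metrics = metrics, cv = cv),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> model %s, %d fold scores\n", x$model,
              nrow(x$scores)))
  print(round(x$mean_scores, 4))
  invisible(x)
}
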