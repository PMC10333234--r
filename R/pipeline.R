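#' Configuration of an end-to-end analysis run
#'
#' Bundles everything [run_pipeline()] needs: the cohort source (a
#' [cohort_config()] to simulate, or a directory written by
#' [write_cohort()]), the sampling strategies to evaluate, preprocessing
#' toggles, fingerprinting/prediction/ROPE settings and the output
#' directory. A `full` sampling spec is appended automatically when absent,
#' since the ROPE comparison is always against full FC.
#'
#' @param cohort a [cohort_config()] (ignored when `input_dir` is given).
#' @param input_dir optional cohort directory to load instead of
#'   simulating.
#' @param sampling_specs list of [sampling_spec()] objects.
#' @param clean run detrend + bandpass cleaning on every run (off by
#'   default: simulated cohorts are generated clean).
#' @param band bandpass edges in Hz when cleaning.
#' @param n_boot bootstrap resamples for fingerprint confidence intervals
#'   (0 disables the bootstrap).
#' @param cv_scheme,k_outer,n_repeats,k_inner cross-validation layout (see
#'   [cv_spec()]); family grouping is taken from the cohort.
#' @param model prediction model (see [run_prediction_cv()]).
#' @param grid hyperparameter grid; `NULL` for the model default.
#' @param rope_halfwidth equivalence half-width for the ROPE comparison.
#' @param do_prediction run the prediction/ROPE stage.
#' @param seed master seed for bootstrap and CV fold randomness.
#' @param out_dir results directory.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(cohort = NULL, input_dir = NULL,
                            sampling_specs = list(sampling_spec("full")),
                            clean = FALSE, band = c(0.008, 0.08),
                            n_boot = 0L,
                            cv_scheme = "grouped_kfold", k_outer = 10L,
                            n_repeats = 1L, k_inner = 5L,
                            model = "kernel_ridge", grid = NULL,
                            rope_halfwidth = 0.05, do_prediction = TRUE,
                            seed = 1L, out_dir = tempfile("cofluct_run")) {
  if (is.null(cohort) && is.null(input_dir))
    stop("provide either a cohort_config or an input_dir")
  if (!any(vapply(sampling_specs, function(s) s$strategy == "full", logical(1))))
    sampling_specs <- c(sampling_specs, list(sampling_spec("full")))
  structure(list(cohort = cohort, input_dir = input_dir,
                 sampling_specs = sampling_specs, clean = clean, band = band,
                 n_boot = as.integer(n_boot), cv_scheme = cv_scheme,
                 k_outer = as.integer(k_outer), n_repeats = as.integer(n_repeats),
                 k_inner = as.integer(k_inner), model = model, grid = grid,
                 rope_halfwidth = rope_halfwidth,
                 do_prediction = isTRUE(do_prediction),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

# run a pipeline stage, prefixing failures with the stage name
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full co-fluctuation analysis pipeline
#'
#' Simulates or loads a cohort, optionally cleans every run, and for every
#' sampling strategy: estimates per-run FC from the selected frames,
#' averages across encodings (identification input) and across all runs
#' (prediction input), computes fingerprinting metrics (with optional
#' bootstrap), predicts every phenotype under nested family-grouped CV,
#' compares each strategy's per-fold scores against full FC with the
#' Bayesian ROPE, and correlates FC with structural connectivity. The
#' RSS-motion diagnostic is computed for every run. Results are written as
#' JSON plus per-strategy FC edge tables; everything is deterministic
#' under the configured seeds (no timestamps in outputs).
#'
#' @param config an [analysis_config()].
#' @return the results list, invisibly; files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- stage("synthetic_data",
    if (!is.null(config$input_dir)) read_cohort(config$input_dir)
    else generate_cohort(config$cohort))
  subjects <- cohort_subjects(cohort)
  n <- length(subjects)

  if (config$clean)
    cohort$runs <- stage("preprocess", lapply(cohort$runs, clean_run,
                                              band = config$band))

  # RSS-motion diagnostic over all runs
  ets_all <- stage("ets_sampling", lapply(cohort$runs, compute_ets))
  rss_all <- lapply(ets_all, compute_rss)
  rss_fd <- stage("preprocess", vapply(names(cohort$runs), function(key)
    rss_motion_correlation(rss_all[[key]], cohort$fd[[key]]), numeric(1)))

  targets <- setdiff(names(cohort$phenotypes), "subject")
  conf_cols <- intersect(c("age", "sex", "fd_mean"), names(cohort$confounds))
  confounds <- as.matrix(cohort$confounds[, conf_cols, drop = FALSE])
  cv <- cv_spec(config$cv_scheme, k_outer = config$k_outer,
                n_repeats = config$n_repeats, k_inner = config$k_inner,
                groups = if (config$cv_scheme == "grouped_kfold")
                  unname(cohort$families[subjects]),
                seed = child_seed(config$seed, 7L))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list(seed = config$seed, n_subjects = n,
                  rss_fd = list(mean = mean(rss_fd), sd = stats::sd(rss_fd)),
                  specs = list())
  pred_fold_scores <- list()

  for (spec in config$sampling_specs) {
    label <- spec_label(spec)
    rankings <- lapply(rss_all, rank_time_points)
    fcs <- stage("ets_sampling", lapply(names(cohort$runs), function(key) {
      run <- cohort$runs[[key]]
      fc <- estimate_fc(run, select_time_points(rankings[[key]], spec))
      fc$provenance$spec <- label
      fc
    }))

    per_day <- aggregate_fc(fcs, "per_day")
    n_edges <- length(per_day[[1]]$vec)
    day_mat <- function(day) {
      m <- t(vapply(subjects, function(s)
        per_day[[sprintf("%s_d%d", s, day)]]$vec, numeric(n_edges)))
      rownames(m) <- subjects
      m
    }
    fp <- stage("fingerprint", fingerprint_metrics(day_mat(1), day_mat(2)))
    spec_res <- list(fingerprint = fp)
    if (config$n_boot > 0) {
      bt <- stage("fingerprint",
                  bootstrap_identification(day_mat(1), day_mat(2),
                                           n_boot = config$n_boot,
                                           seed = child_seed(config$seed, 11L)))
      ci <- function(v) as.numeric(stats::quantile(v, c(0.025, 0.975)))
      spec_res$bootstrap <- list(i_acc_ci = ci(bt$i_acc),
                                 i_diff_ci = ci(bt$i_diff))
    }

    per_subject <- aggregate_fc(fcs, "per_subject")
    features <- t(vapply(subjects, function(s) per_subject[[s]]$vec,
                         numeric(n_edges)))
    rownames(features) <- subjects
    utils::write.table(
      data.frame(subject = subjects, features, check.names = FALSE),
      file.path(config$out_dir, paste0("fc_", label, ".tsv")),
      sep = "\t", row.names = FALSE)

    if (config$do_prediction) {
      spec_res$prediction <- list()
      for (tg in targets) {
        pr <- stage("prediction", run_prediction_cv(
          features, cohort$phenotypes[[tg]], confounds = confounds, cv = cv,
          model = config$model, grid = config$grid))
        key_metric <- if (config$model == "ridge_classifier") "accuracy"
                      else "pearson_r"
        pred_fold_scores[[label]][[tg]] <- pr$scores[[key_metric]]
        spec_res$prediction[[tg]] <- list(
          mean_scores = as.list(pr$mean_scores),
          fold_scores = pr$scores[[key_metric]],
          chosen = pr$chosen$hyperparameter)
      }
    }

    if (!is.null(cohort$sc)) {
      spec_res$sc_fc_correlation <- stage("sc_coupling", mean(vapply(
        subjects, function(s)
          sc_fc_correlation(per_subject[[s]], cohort$sc[[s]]), numeric(1))))
    }
    results$specs[[label]] <- spec_res
  }

  # ROPE: every non-full strategy against full FC on matched folds
  if (config$do_prediction && "full" %in% names(pred_fold_scores)) {
    n_test <- n / config$k_outer
    for (label in setdiff(names(pred_fold_scores), "full")) {
      for (tg in names(pred_fold_scores[[label]])) {
        sx <- pred_fold_scores[[label]][[tg]]
        sy <- pred_fold_scores[["full"]][[tg]]
        ok <- is.finite(sx) & is.finite(sy)   # folds scoreable for both models
        if (sum(ok) < 2) {
          results$specs[[label]]$rope_vs_full[[tg]] <- list(skipped = TRUE)
          next
        }
        rp <- stage("model_compare", rope_compare(
          sx[ok], sy[ok],
          rope_halfwidth = config$rope_halfwidth,
          n_train = n - n_test, n_test = n_test))
        results$specs[[label]]$rope_vs_full[[tg]] <- list(
          p_left = rp$p_left, p_rope = rp$p_rope, p_right = rp$p_right,
          decision = rp$decision)
      }
    }
  }

  jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  writeLines(c(
    sprintf("cofluct %s", as.character(utils::packageVersion("cofluct"))),
    sprintf("seed: %d", config$seed),
    sprintf("sampling specs: %s",
            paste(vapply(config$sampling_specs, spec_label, character(1)),
                  collapse = ", ")),
    sprintf("cleaning: %s (band %g-%g Hz, Butterworth order 5, zero-phase)",
            config$clean, config$band[1], config$band[2]),
    sprintf("cv: %s k_outer=%d n_repeats=%d k_inner=%d", config$cv_scheme,
            config$k_outer, config$n_repeats, config$k_inner),
    sprintf("model: %s; rope halfwidth: %g", config$model,
            config$rope_halfwidth),
    "z-scoring: population sd; FC averaging: raw correlations;",
    "argmax ties: failed identification; inner-CV ties: smallest hyperparameter"),
    file.path(config$out_dir, "log.txt"))
  invisible(results)
}
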