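#' Cross-day FC similarity matrix
#'
#' Entry (a, b) is the Pearson correlation between subject a's day-1 FC
#' edge vector and subject b's day-2 FC edge vector. Subject order is
#' shared across both axes, so the diagonal holds the within-subject
#' (self) similarities.
#'
#' @param day1,day2 subject x edge matrices (rows aligned to the same
#'   subject list) or lists of [fc_matrix()] whose `vec`s are stacked.
#' @return object of class `similarity_matrix`: a square numeric matrix
#'   with subject ids as dimnames.
#' @export
similarity_matrix <- function(day1, day2) {
  day1 <- as_fc_rows(day1)
  day2 <- as_fc_rows(day2)
  if (nrow(day1) != nrow(day2) || ncol(day1) != ncol(day2))
    stop("day1 and day2 must hold the same subjects and edge count")
  if (any(apply(day1, 1, stats::sd) == 0) || any(apply(day2, 1, stats::sd) == 0))
    stop("zero-variance FC vector")
  s <- stats::cor(t(day1), t(day2))
  dimnames(s) <- list(rownames(day1), rownames(day2))
  class(s) <- c("similarity_matrix", class(s))
  s
}

# coerce a list of fc_matrix or a numeric matrix to subject x edge rows
as_fc_rows <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "fc_matrix"))) {
    m <- t(vapply(x, function(fc) fc$vec, numeric(length(x[[1]]$vec))))
    rn <- names(x) %||% vapply(x, function(fc) fc$provenance$subject %||% "", character(1))
    rownames(m) <- rn
    return(m)
  }
  stop("expected a subject x edge matrix or a list of fc_matrix objects")
}

#' Identification accuracy
#'
#' Fraction of subjects whose cross-day similarity is maximal with
#' themselves, computed in both directions (day 1 as source over rows, day
#' 2 as source over columns) and averaged. A tied maximum counts as a
#' failed identification.
#'
#' @param sim a [similarity_matrix()].
#' @return identification accuracy in \[0, 1\].
#' @export
identification_accuracy <- function(sim) {
  n <- nrow(sim)
  if (is.null(n) || n < 2 || ncol(sim) != n)
    stop("need a square similarity matrix with n >= 2")
  hit <- function(v, k) {
    m <- max(v)
    v[k] == m && sum(v == m) == 1L
  }
  acc1 <- mean(vapply(seq_len(n), function(a) hit(sim[a, ], a), logical(1)))
  acc2 <- mean(vapply(seq_len(n), function(b) hit(sim[, b], b), logical(1)))
  (acc1 + acc2) / 2
}

#' Differential identifiability
#'
#' I_self is the mean within-subject (diagonal) similarity, I_other the
#' mean between-subject (all off-diagonal) similarity, and
#' I_diff = (I_self - I_other) * 100.
#'
#' @param sim a [similarity_matrix()].
#' @return list with `i_self`, `i_other`, `i_diff`.
#' @export
differential_identifiability <- function(sim) {
  n <- nrow(sim)
  if (is.null(n) || n < 2 || ncol(sim) != n)
    stop("need a square similarity matrix with n >= 2")
  i_self <- mean(diag(sim))
  i_other <- mean(sim[row(sim) != col(sim)])
  list(i_self = i_self, i_other = i_other, i_diff = (i_self - i_other) * 100)
}

#' Fingerprinting metrics for one day-1/day-2 FC pair
#'
#' @param day1,day2 as in [similarity_matrix()].
#' @return list with `i_acc`, `i_self`, `i_other`, `i_diff`.
#' @export
fingerprint_metrics <- function(day1, day2) {
  sim <- similarity_matrix(day1, day2)
  c(list(i_acc = identification_accuracy(sim)),
    differential_identifiability(sim))
}

#' Bootstrap distribution of fingerprinting metrics
#'
#' Resamples subjects with replacement `n_boot` times; each resample keeps
#' only its unique subjects and recomputes identification accuracy and
#' differential identifiability on that subset. Resamples with fewer than
#' two unique subjects are redrawn. The full similarity matrix is computed
#' once and subset per resample (equivalent to recomputing from the FC
#' vectors).
#'
#' @param day1,day2 as in [similarity_matrix()].
#' @param n_boot number of resamples (default 1000).
#' @param seed RNG seed.
#' @return object of class `bootstrap_result`: data.frame with one row per
#'   resample (`i_acc`, `i_self`, `i_other`, `i_diff`, `n_unique`) plus
#'   attributes `n_boot` and `seed`.
#' @export
bootstrap_identification <- function(day1, day2, n_boot = 1000L, seed = 1L) {
  sim <- similarity_matrix(day1, day2)
  n <- nrow(sim)
  if (n < 2) stop("need at least 2 subjects")
  res <- with_seed(seed, {
    one <- function() {
      repeat {
        keep <- unique(sample.int(n, n, replace = TRUE))
        if (length(keep) >= 2) break
      }
      sub <- sim[keep, keep, drop = FALSE]
      di <- differential_identifiability(sub)
      c(i_acc = identification_accuracy(sub), i_self = di$i_self,
        i_other = di$i_other, i_diff = di$i_diff, n_unique = length(keep))
    }
    as.data.frame(t(vapply(seq_len(n_boot), function(b) one(), numeric(5))))
  })
  attr(res, "n_boot") <- as.integer(n_boot)
  attr(res, "seed") <- as.integer(seed)
  class(res) <- c("bootstrap_result", class(res))
  res
}

#' Compare two bootstrapped metric series
#'
#' Two-tailed Wilcoxon signed-rank test on the paired per-resample
#' differences (e.g. HACF-derived vs LACF-derived identification
#' accuracy), with Bonferroni correction over the number of thresholds
#' compared. If every paired difference is zero the test is undefined and
#' p = 1 is reported with a flag.
#'
#' @param a,b equal-length paired metric series.
#' @param n_comparisons Bonferroni factor.
#' @param alpha significance level after correction.
#' @return list with `statistic`, `p_raw`, `p_bonferroni`, `significant`,
#'   `degenerate`.
#' @export
compare_conditions <- function(a, b, n_comparisons = 1L, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired series must have equal length")
  d <- a - b
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_raw = 1, p_bonferroni = 1,
                significant = FALSE, degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            alternative = "two.sided"))
  p_b <- min(1, wt$p.value * n_comparisons)
  list(statistic = unname(wt$statistic), p_raw = wt$p.value,
       p_bonferroni = p_b, significant = p_b < alpha, degenerate = FALSE)
}
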