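#' Bayesian region-of-practical-equivalence model comparison
#'
#' Bayesian correlated t-test on the paired per-fold score differences
#' d_i = x_i - y_i of two models evaluated on the same cross-validation
#' folds. The posterior of the mean difference is Student-t with location
#' mean(d), scale sqrt((1/k + n_test/n_train) * var(d)) and k - 1 degrees
#' of freedom; the n_test/n_train term corrects for the overlap of
#' training sets across folds (Nadeau-Bengio). With `correlated = FALSE`
#' the plain paired posterior scale sqrt(var(d)/k) is used instead.
#'
#' The three reported probabilities are the posterior mass below
#' `-rope_halfwidth` (model y practically better), inside
#' `[-rope_halfwidth, rope_halfwidth]` (practically equivalent) and above
#' (model x practically better). The half-width is in the score's own
#' units, so 0.05 means 5 accuracy points or 0.05 correlation units.
#'
#' @param scores_x,scores_y equal-length paired per-fold scores (length >=
#'   2).
#' @param rope_halfwidth half-width of the equivalence region.
#' @param n_train,n_test training-/test-set sizes of one CV split
#'   (required when `correlated = TRUE`).
#' @param correlated apply the CV-overlap correction (default TRUE).
#' @return object of class `rope_result` with `p_left` (P(x < y)),
#'   `p_rope` (P(x = y)), `p_right` (P(x > y)) and `decision` (`"<"`,
#'   `"="` or `">"`, the region with the largest posterior mass, ties
#'   toward `"="`).
#' @export
rope_compare <- function(scores_x, scores_y, rope_halfwidth = 0.05,
                         n_train = NULL, n_test = NULL, correlated = TRUE) {
  k <- length(scores_x)
  if (length(scores_y) != k) stop("paired scores must have equal length")
  if (k < 2) stop("need at least 2 paired fold scores")
  if (rope_halfwidth < 0) stop("rope_halfwidth must be nonnegative")
  if (correlated && (is.null(n_train) || is.null(n_test)))
    stop("correlated posterior needs n_train and n_test")
  d <- scores_x - scores_y
  m <- mean(d)
  v <- stats::var(d)
  if (v == 0) {
    p <- c(left = as.numeric(m < -rope_halfwidth),
           rope = as.numeric(abs(m) <= rope_halfwidth),
           right = as.numeric(m > rope_halfwidth))
  } else {
    corr <- if (correlated) 1 / k + n_test / n_train else 1 / k
    s <- sqrt(corr * v)
    lo <- stats::pt((-rope_halfwidth - m) / s, df = k - 1)
    hi <- stats::pt((rope_halfwidth - m) / s, df = k - 1)
    p <- c(left = lo, rope = hi - lo, right = 1 - hi)
  }
  decision <- if (p["rope"] >= max(p)) "="
              else if (p["left"] > p["right"]) "<" else ">"
  structure(list(p_left = unname(p["left"]), p_rope = unname(p["rope"]),
                 p_right = unname(p["right"]),
                 rope_halfwidth = rope_halfwidth, decision = decision),
            class = "rope_result")
}

#' @export
print.rope_result <- function(x, ...) {
  cat(sprintf("<rope_result> P(x<y) = %.4f  P(x=y) = %.4f  P(x>y) = %.4f  decision: %s\n",
              x$p_left, x$p_rope, x$p_right, x$decision))
  invisible(x)
}
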