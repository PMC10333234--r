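#' Canonical edge index for a parcellation
#'
#' Edges are the unordered parcel pairs (i, j) with i < j, enumerated
#' row-major over the upper triangle: (1,2), (1,3), ..., (1,p), (2,3), ...
#' Every edge vector in the package (FC, ETS columns, SC) follows this order.
#'
#' @param n_parcels number of parcels p.
#' @return data.frame with integer columns `i`, `j` and a `label` "i_j",
#'   one row per edge, n_edges = p (p - 1) / 2.
#' @export
edge_index <- function(n_parcels) {
  stopifnot(n_parcels >= 2)
  i <- unlist(lapply(seq_len(n_parcels - 1L), function(a) rep.int(a, n_parcels - a)))
  j <- unlist(lapply(seq_len(n_parcels - 1L), function(a) seq.int(a + 1L, n_parcels)))
  data.frame(i = i, j = j, label = paste0(i, "_", j))
}

#' Vectorise a symmetric parcel-by-parcel matrix in canonical edge order
#'
#' @param m symmetric matrix.
#' @return numeric vector of the upper-triangle entries in [edge_index()]
#'   order.
#' @export
upper_vec <- function(m) {
  idx <- edge_index(nrow(m))
  m[cbind(idx$i, idx$j)]
}

#' Rebuild a symmetric matrix from its canonical edge vector
#'
#' @param v edge vector in [edge_index()] order.
#' @param diag_value value placed on the diagonal (1 for correlation
#'   matrices, 0 for streamline counts).
#' @return symmetric matrix.
#' @export
unvec_sym <- function(v, diag_value = 1) {
  p <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(p - round(p)) > 1e-8)
    stop("edge vector length ", length(v), " is not p*(p-1)/2 for integer p")
  p <- as.integer(round(p))
  m <- matrix(0, p, p)
  idx <- edge_index(p)
  m[cbind(idx$i, idx$j)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Pearson product-moment correlation
#'
#' Computed from the raw sums, n*sum(xy) - sum(x)*sum(y) over the product of
#' the root corrected sums of squares. Equivalent to [stats::cor()] for
#' complete numeric vectors; kept explicit because it is the similarity
#' primitive the whole pipeline is built on.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  sx <- sum(x); sy <- sum(y)
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  if (den == 0) stop("zero variance input to pearson_r")
  (n * sum(x * y) - sx * sy) / den
}

# z-score with population (ddof = 0) standard deviation; this convention
# makes the time-mean of the edge time series equal full-run Pearson FC
# exactly.
zscore_pop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) stop("zero-variance series cannot be z-scored")
  (x - mu) / s
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream-specific child seed from a master seed, kept within the
# 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream) %% 2147483647
}
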