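#' Structural connectivity matrix
#'
#' Parcel x parcel streamline-count matrix from diffusion tractography:
#' symmetric, nonnegative, zero diagonal, with the canonical edge-vector
#' view shared with [fc_matrix()].
#'
#' @param matrix symmetric nonnegative matrix with zero diagonal.
#' @param log1p apply a log(1 + x) transform to the counts.
#' @return object of class `sc_matrix` with fields `matrix` and `vec`.
#' @export
sc_matrix <- function(matrix, log1p = FALSE) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (any(matrix < 0)) stop("streamline counts must be nonnegative")
  if (max(abs(matrix - t(matrix))) > 1e-8) stop("SC matrix must be symmetric")
  if (any(diag(matrix) != 0)) stop("SC matrix must have a zero diagonal")
  if (log1p) matrix <- log1p(matrix)
  structure(list(matrix = matrix, vec = upper_vec(matrix)),
            class = "sc_matrix")
}

#' Structure-function edge correlation
#'
#' Pearson correlation between a subject's FC edge vector and their SC
#' edge vector (shared parcel order).
#'
#' @param fc an [fc_matrix()] or edge vector.
#' @param sc an [sc_matrix()] or edge vector.
#' @return correlation coefficient.
#' @export
sc_fc_correlation <- function(fc, sc) {
  f <- if (inherits(fc, "fc_matrix")) fc$vec else as.numeric(fc)
  s <- if (inherits(sc, "sc_matrix")) sc$vec else as.numeric(sc)
  if (length(f) != length(s)) stop("FC and SC edge vectors differ in length")
  pearson_r(f, s)
}

#' Remove structural connectivity from an FC edge vector
#'
#' Per subject, ordinary least squares of the FC edge vector on
#' `[1, sc.vec]` across edges; the residual vector becomes the subject's
#' structure-free FC feature row.
#'
#' @param fc an [fc_matrix()] or edge vector.
#' @param sc an [sc_matrix()] or edge vector; must be nonconstant.
#' @return numeric residual edge vector.
#' @export
regress_sc_from_fc <- function(fc, sc) {
  f <- if (inherits(fc, "fc_matrix")) fc$vec else as.numeric(fc)
  s <- if (inherits(sc, "sc_matrix")) sc$vec else as.numeric(sc)
  if (length(f) != length(s)) stop("FC and SC edge vectors differ in length")
  if (stats::sd(s) == 0) stop("constant SC vector is collinear with the intercept")
  x <- cbind(1, s)
  as.numeric(f - x %*% qr.solve(x, f))
}
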