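#' Shift a linear-scale matrix to strictly positive values
#'
#' Negative (or zero) background-subtracted signals are made positive
#' before log transformation by adding the single global constant
#' \eqn{|\min(m)| + 2} to every entry whenever the global minimum is
#' \eqn{\le 0}.  An all-positive matrix is returned unchanged.  One global
#' shift (not per column) preserves between-array relationships for the
#' normalization that follows.
#'
#' @param m Numeric matrix (or vector) on the linear scale.
#' @return Same shape as \code{m}; after a shift the minimum is exactly 2.
#' @export
shift_positive <- function(m) {
  if (!all(is.finite(m))) stop("non-finite values in input")
  mn <- min(m)
  if (mn <= 0) m + abs(mn) + 2 else m
}

#' Scale each array to its 75th percentile
#'
#' Divides every column by its own 75th percentile (linear interpolation
#' between order statistics, i.e. the quantile at position
#' \eqn{1 + (n-1)q}; `stats::quantile` type 7) so that afterwards each
#' array's 75th percentile equals 1.  The 75th percentile is preferred to
#' the mean as it is insensitive to bright outliers, and to the median
#' under the assumption that roughly half the microRNAs are unexpressed.
#'
#' @param m Numeric matrix on the linear scale, columns = arrays.
#' @return Scaled matrix.
#' @export
scale_to_percentile75 <- function(m) {
  if (!all(is.finite(m))) stop("non-finite values in input")
  p75 <- apply(m, 2L, stats::quantile, probs = 0.75, names = FALSE,
               type = 7L)
  if (any(p75 <= 0))
    stop("non-positive 75th percentile in column(s) ",
         paste(which(p75 <= 0), collapse = ", "),
         "; apply shift_positive() first")
  sweep(m, 2L, p75, "/")
}

#' Quantile-normalize arrays to a common distribution
#'
#' Forces every column to share the same sorted value multiset: each value
#' is replaced by the mean of the same-rank values across arrays, with
#' within-column tied values receiving the mean of the reference values
#' their ranks span (the Bolstad convention, as implemented by
#' \code{limma::normalizeQuantiles}).
#'
#' @param m Numeric matrix with at least two columns and no missing values.
#' @return Normalized matrix of the same shape, dimnames preserved.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (ncol(m) < 2L)
    stop("quantile normalization needs at least 2 arrays")
  if (!all(is.finite(m))) stop("non-finite values in input")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Log2-transform a positive matrix
#'
#' @param m Numeric matrix of strictly positive values.
#' @return \code{log2(m)}.
#' @export
log2_transform <- function(m) {
  bad <- which(!(m > 0), arr.ind = is.matrix(m))
  if (length(bad)) {
    loc <- if (is.matrix(m))
      sprintf("row %d, column %d", bad[1L, 1L], bad[1L, 2L])
    else sprintf("position %d", bad[[1L]])
    stop("non-positive entry at ", loc, "; cannot log2-transform")
  }
  log2(m)
}
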