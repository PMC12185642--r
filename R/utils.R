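#' Unit conversion between mmHg and Pa
#'
#' All internal computations use SI units (Pa). Clinical pressures arrive in
#' mmHg; conversion uses 1 mmHg = 133.322 Pa.
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the other unit.
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(x) x / 133.322

#' Trapezoidal quadrature weights over one period with wrap closure
#'
#' Sample times need not include the wrap point t[1] + T; the signal is
#' treated as periodic and the segment from the last sample back to the first
#' (length T - (t[n] - t[1])) closes the cycle. Weights sum to T.
#'
#' @param t strictly increasing sample times (s) spanning at most one period.
#' @param period the period T (s).
#' @return numeric vector of weights, one per sample.
#' @export
cycle_weights <- function(t, period) {
  n <- length(t)
  if (n < 2L) stop("need at least 2 samples for cycle quadrature")
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing")
  span <- t[n] - t[1]
  if (span > period + 1e-12 * period) {
    stop("samples span more than one period")
  }
  d <- diff(t)
  wrap <- period - span
  d <- c(d, wrap)                       # segment k joins sample k to k+1 (wrapped)
  w <- (d + c(wrap, d[-n])) / 2
  w
}

#' Cycle mean of a periodic signal (trapezoid with wrap closure)
#'
#' @param t sample times.
#' @param x numeric vector (length(t)) or matrix/array whose FIRST dimension
#'   is time.
#' @param period the period T.
#' @return scalar, vector or array: the time dimension is averaged out.
#' @export
cycle_mean <- function(t, x, period) {
  w <- cycle_weights(t, period) / period
  if (is.null(dim(x))) {
    if (length(x) != length(t)) stop("length mismatch between t and x")
    return(sum(w * x))
  }
  d <- dim(x)
  if (d[1] != length(t)) stop("first dimension of x must be time")
  m <- matrix(x, nrow = d[1])
  out <- colSums(m * w)
  if (length(d) > 2L) array(out, d[-1]) else out
}

#' @keywords internal
row_norms <- function(m) sqrt(rowSums(m * m))

#' @keywords internal
cross3 <- function(a, b) {
  # row-wise cross product of n x 3 matrices
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
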