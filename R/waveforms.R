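#' Resample a waveform to a uniform time grid
#'
#' Cubic-spline resampling (periodic end conditions for periodic waveforms,
#' natural otherwise) onto the uniform grid 0, dt, 2 dt, ... covering
#' `[0, T)`. Mirrors the common practice of spline-interpolating a digitised
#' Doppler waveform to the solver timestep (e.g. 1 ms).
#'
#' @param w a [waveform()] with at least 4 samples.
#' @param dt target spacing (s), `0 < dt < T`.
#' @return a [waveform()] on the uniform grid.
#' @export
resample_waveform <- function(w, dt) {
  stopifnot(inherits(w, "waveform"))
  if (dt <= 0) stop("dt must be positive")
  if (dt >= w$period) stop("dt must be smaller than the period")
  if (length(w$times) < 4L) stop("need at least 4 samples for cubic resampling")
  n <- floor(w$period / dt + 1e-9)
  t_new <- (seq_len(n) - 1) * dt
  waveform(t_new, eval_waveform(w, t_new), w$period, units = w$units,
           periodic = w$periodic)
}

#' Convert a velocity waveform to a volumetric flow waveform
#'
#' Multiplies a cross-sectional mean velocity (m/s) by the vessel
#' cross-sectional area, as done when deriving a reference flow curve from a
#' Doppler velocity trace and an imaged lumen area.
#'
#' @param v a [waveform()] with units "m/s".
#' @param area cross-sectional area (m^2), positive.
#' @return a [waveform()] with units "m3/s" on the same time grid.
#' @export
velocity_to_flow <- function(v, area) {
  stopifnot(inherits(v, "waveform"))
  if (!identical(v$units, "m/s")) stop("input waveform must carry units m/s")
  if (area <= 0) stop("area must be positive")
  waveform(v$times, v$values * area, v$period, units = "m3/s",
           periodic = v$periodic)
}

#' Pointwise percentage-difference statistics between two waveforms
#'
#' Computes d_k = 100 (test_k - ref_k) / ref_k on the reference grid (the test
#' waveform is spline-evaluated there if its grid differs) and returns the
#' mean and the population standard deviation of d. Samples where
#' |ref| < 1e-6 max|ref| are excluded and counted: with a near-zero
#' denominator the pointwise ratio is meaningless.
#'
#' @param reference reference [waveform()] (denominator).
#' @param test comparison [waveform()].
#' @return list of class `waveform_comparison`: `mean_pct`, `sd_pct`, `n`,
#'   `n_excluded`.
#' @export
waveform_difference_stats <- function(reference, test) {
  stopifnot(inherits(reference, "waveform"), inherits(test, "waveform"))
  tv <- if (length(test$times) == length(reference$times) &&
            max(abs(test$times - reference$times)) < 1e-12) {
    test$values
  } else {
    eval_waveform(test, reference$times)
  }
  rv <- reference$values
  eps <- 1e-6 * max(abs(rv))
  keep <- abs(rv) > eps
  if (!any(keep)) stop("no comparable samples: reference is (near) zero everywhere")
  d <- 100 * (tv[keep] - rv[keep]) / rv[keep]
  m <- mean(d)
  s <- sqrt(mean((d - m)^2))              # population SD
  structure(list(mean_pct = m, sd_pct = s, n = sum(keep),
                 n_excluded = sum(!keep)),
            class = "waveform_comparison")
}

#' @export
print.waveform_comparison <- function(x, ...) {
  cat(sprintf("mean %% difference: %.4g%%, SD: %.4g%% (n = %d, excluded = %d)\n",
              x$mean_pct, x$sd_pct, x$n, x$n_excluded))
  invisible(x)
}

#' First cycle at which per-cycle peaks have converged
#'
#' Cyclic periodicity criterion: the smallest k >= 2 with
#' |p_k - p_{k-1}| / |p_{k-1}| below `tol` (default 1%, the usual "< 1% change
#' in peak systolic pressure between subsequent cycles"). Returns
#' `NA_integer_` if no cycle satisfies it.
#'
#' @param peak_values ordered per-cycle peak values (e.g. systolic pressures).
#' @param tol relative tolerance, default 0.01.
#' @return integer cycle index (1-based) or `NA_integer_`.
#' @export
cyclic_periodicity_index <- function(peak_values, tol = 0.01) {
  if (length(peak_values) < 2L) stop("need at least 2 cycles")
  if (any(!is.finite(peak_values))) stop("non-finite peak value")
  for (k in 2:length(peak_values)) {
    if (abs(peak_values[k] - peak_values[k - 1]) <
        tol * abs(peak_values[k - 1])) {
      return(k)
    }
  }
  NA_integer_
}

#' Cycle mean of a waveform (trapezoid with wrap closure)
#'
#' @param w a [waveform()].
#' @return scalar mean value over one period.
#' @export
waveform_mean <- function(w) {
  stopifnot(inherits(w, "waveform"))
  cycle_mean(w$times, w$values, w$period)
}
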