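#' Time-resolved velocity field on a tetrahedral mesh
#'
#' Velocity 3-vectors per node, sampled over one cardiac cycle. The sample
#' times need not include the wrap point t[1] + T: all cycle integrals close
#' the period with the trapezoidal wrap segment.
#'
#' @param mesh a [volume_mesh()].
#' @param times strictly increasing sample times (s) spanning at most one
#'   period; at least 3 samples.
#' @param velocity numeric array of dim (n_nodes, 3, n_times), m/s.
#' @param period cycle period T (s).
#' @return object of class `volume_series`.
#' @export
volume_series <- function(mesh, times, velocity, period) {
  stopifnot(inherits(mesh, "volume_mesh"))
  check_series_times(times, period)
  velocity <- as_field_array(velocity, nrow(mesh$nodes), length(times))
  structure(list(mesh = mesh, times = times, velocity = velocity,
                 period = period),
            class = "volume_series")
}

#' Time-resolved wall shear stress on a lumen surface
#'
#' WSS 3-vectors per surface node over one cycle (Pa). On construction each
#' sample is projected onto the local tangent plane (tau must be tangential);
#' the largest normal deviation removed is recorded in
#' `max_normal_deviation`.
#'
#' @param mesh a [surface_mesh()].
#' @param times strictly increasing sample times (s); at least 3 samples.
#' @param wss numeric array of dim (n_nodes, 3, n_times), Pa.
#' @param period cycle period T (s).
#' @return object of class `wss_series`.
#' @export
wss_series <- function(mesh, times, wss, period) {
  stopifnot(inherits(mesh, "surface_mesh"))
  check_series_times(times, period)
  wss <- as_field_array(wss, nrow(mesh$nodes), length(times))
  n <- mesh$normals
  max_dev <- 0
  for (k in seq_along(times)) {
    tk <- wss[, , k]
    comp <- rowSums(tk * n)                  # normal component
    dev <- max(abs(comp))
    if (dev > max_dev) max_dev <- dev
    wss[, , k] <- tk - n * comp              # project onto tangent plane
  }
  structure(list(mesh = mesh, times = times, wss = wss, period = period,
                 max_normal_deviation = max_dev),
            class = "wss_series")
}

#' @keywords internal
check_series_times <- function(times, period) {
  if (length(times) < 3L) stop("need at least 3 time samples")
  if (any(diff(times) <= 0)) stop("sample times must be strictly increasing")
  if (times[length(times)] - times[1] > period * (1 + 1e-12)) {
    stop("samples span more than one period")
  }
  invisible(TRUE)
}

#' @keywords internal
as_field_array <- function(x, n_nodes, n_times) {
  x <- if (is.array(x)) x else array(x, dim = c(n_nodes, 3, n_times))
  if (!identical(dim(x), c(n_nodes, 3L, n_times)) &&
      !identical(dim(x), as.integer(c(n_nodes, 3, n_times)))) {
    stop(sprintf("field must have dim (%d, 3, %d)", n_nodes, n_times))
  }
  storage.mode(x) <- "double"
  x
}

#' Periodic scalar waveform
#'
#' A sampled scalar time series (flow, velocity or pressure) over one period.
#'
#' @param times strictly increasing sample times (s) within `[0, period]`.
#' @param values numeric values, same length.
#' @param period the period T (s).
#' @param units one of "m/s", "m3/s", "Pa" (bookkeeping tag used by
#'   [velocity_to_flow()]).
#' @param periodic logical; if `TRUE` interpolation wraps around the period.
#' @return object of class `waveform`.
#' @export
waveform <- function(times, values, period, units = "m3/s", periodic = TRUE) {
  if (length(times) != length(values)) stop("times and values differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1] < -1e-12 || times[length(times)] > period * (1 + 1e-12)) {
    stop("times must lie within [0, period]")
  }
  if (any(!is.finite(values))) stop("waveform values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 period = period, units = units, periodic = isTRUE(periodic)),
            class = "waveform")
}

#' Evaluate a waveform at arbitrary times by spline interpolation
#'
#' Cubic spline with periodic end conditions when the waveform is periodic
#' (the wrap knot at t[1] + T reuses the first value), natural end conditions
#' otherwise. Evaluation times are reduced modulo the period for periodic
#' waveforms.
#'
#' @param w a [waveform()].
#' @param t evaluation times (s).
#' @return numeric vector of values.
#' @export
eval_waveform <- function(w, t) {
  stopifnot(inherits(w, "waveform"))
  tt <- w$times
  vv <- w$values
  if (w$periodic) {
    has_wrap <- abs((tt[length(tt)] - tt[1]) - w$period) < 1e-12 * w$period
    if (!has_wrap) {
      tt <- c(tt, tt[1] + w$period)
      vv <- c(vv, vv[1])
    } else if (abs(vv[length(vv)] - vv[1]) > 0) {
      vv[length(vv)] <- vv[1]              # enforce exact periodicity
    }
    if (length(tt) >= 4L) {
      f <- stats::splinefun(tt, vv, method = "periodic")
    } else {
      f <- stats::approxfun(tt, vv, rule = 2)
    }
    f(tt[1] + (t - tt[1]) %% w$period)
  } else {
    method <- if (length(tt) >= 4L) "natural" else "linear"
    if (method == "linear") {
      stats::approx(tt, vv, xout = t, rule = 2)$y
    } else {
      stats::splinefun(tt, vv, method = "natural")(t)
    }
  }
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples over T = %g s (%s)%s\n",
              length(x$times), x$period, x$units,
              if (x$periodic) ", periodic" else ""))
  invisible(x)
}
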