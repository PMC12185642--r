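#' Cycle-averaged velocity field
#'
#' Component-wise trapezoidal time average over one cardiac cycle, with the
#' wrap segment closing the period, divided by T.
#'
#' @param series a [volume_series()].
#' @return n x 3 matrix of mean velocity (m/s).
#' @export
cycle_average_velocity <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  v <- aperm(series$velocity, c(3, 1, 2))     # time first
  cycle_mean(series$times, v, series$period)
}

#' Velocity fluctuations about the cycle mean
#'
#' Instantaneous minus cycle-averaged velocity, per node and sample. With the
#' mean computed from the same series, the cycle average of the returned
#' fluctuations vanishes to integration tolerance. Note that a single-cycle
#' time mean conflates pulsatile and turbulent content; see the package
#' vignette.
#'
#' @param series a [volume_series()].
#' @param mean_velocity n x 3 matrix from [cycle_average_velocity()]; computed
#'   if omitted.
#' @return array (n_nodes, 3, n_times) of fluctuations (m/s).
#' @export
velocity_fluctuations <- function(series, mean_velocity = NULL) {
  stopifnot(inherits(series, "volume_series"))
  if (is.null(mean_velocity)) mean_velocity <- cycle_average_velocity(series)
  if (!all(dim(mean_velocity) == dim(series$velocity)[1:2])) {
    stop("mean_velocity shape does not match the series")
  }
  out <- series$velocity
  for (k in seq_along(series$times)) out[, , k] <- out[, , k] - mean_velocity
  out
}

#' Turbulent kinetic energy field at one instant
#'
#' TKE = 1/2 rho (u'^2 + v'^2 + w'^2) per node (J/m^3), from the fluctuating
#' velocity components at a named instant (conventionally peak systole, the
#' argmax of the inflow waveform).
#'
#' @param fluct n x 3 matrix of fluctuating velocity at the instant (m/s), or
#'   the full fluctuation array with `at` selecting the sample.
#' @param rho blood density (kg/m^3), default 1056.
#' @param at sample index when `fluct` is a 3-d array.
#' @return numeric vector, one TKE value per node (J/m^3).
#' @export
tke_field <- function(fluct, rho = 1056, at = NULL) {
  if (rho <= 0) stop("density must be positive")
  if (length(dim(fluct)) == 3L) {
    if (is.null(at)) stop("supply `at` to pick the instant from a 3-d array")
    fluct <- fluct[, , at]
  }
  0.5 * rho * rowSums(fluct^2)
}

#' Vorticity reconstruction on a tetrahedral mesh
#'
#' Per-tetrahedron constant velocity gradient from linear shape functions,
#' curl per cell, then node values by volume-weighted averaging of incident
#' cells. Exact for affine velocity fields.
#'
#' @param mesh a [volume_mesh()].
#' @param velocity n x 3 matrix, one velocity vector per node (m/s).
#' @return list `node` (n x 3 vorticity, 1/s) and `cell` (m x 3).
#' @export
vorticity_field <- function(mesh, velocity) {
  stopifnot(inherits(mesh, "volume_mesh"))
  velocity <- as.matrix(velocity)
  cells <- mesh$cells
  nodes <- mesh$nodes
  p1 <- nodes[cells[, 1], , drop = FALSE]
  a <- nodes[cells[, 2], , drop = FALSE] - p1
  b <- nodes[cells[, 3], , drop = FALSE] - p1
  cc <- nodes[cells[, 4], , drop = FALSE] - p1
  v6 <- rowSums(a * cross3(b, cc))          # 6 x signed volume (> 0 by ctor)
  g2 <- cross3(b, cc) / v6                  # grad of shape fn of node 2
  g3 <- cross3(cc, a) / v6
  g4 <- cross3(a, b) / v6
  g1 <- -(g2 + g3 + g4)
  v1 <- velocity[cells[, 1], , drop = FALSE]
  v2 <- velocity[cells[, 2], , drop = FALSE]
  v3 <- velocity[cells[, 3], , drop = FALSE]
  v4 <- velocity[cells[, 4], , drop = FALSE]
  # velocity gradient d v_j / d x_i = sum_k g_k[, i] v_k[, j]
  dv <- function(i, j) {
    g1[, i] * v1[, j] + g2[, i] * v2[, j] + g3[, i] * v3[, j] + g4[, i] * v4[, j]
  }
  wc <- cbind(dv(2, 3) - dv(3, 2),
              dv(3, 1) - dv(1, 3),
              dv(1, 2) - dv(2, 1))
  # volume-weighted node averaging
  vol <- mesh$cell_volumes
  wn <- matrix(0, nrow(nodes), 3)
  wsum <- numeric(nrow(nodes))
  for (k in 1:4) {
    acc <- rowsum(cbind(wc * vol, vol), cells[, k])
    idx <- as.integer(rownames(acc))
    wn[idx, ] <- wn[idx, ] + acc[, 1:3]
    wsum[idx] <- wsum[idx] + acc[, 4]
  }
  wn <- wn / pmax(wsum, .Machine$double.xmin)
  list(node = wn, cell = wc)
}

#' Vorticity time series for a velocity series
#'
#' @param series a [volume_series()].
#' @return array (n_nodes, 3, n_times) of nodal vorticity (1/s).
#' @export
vorticity_series <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  out <- array(0, dim(series$velocity))
  for (k in seq_along(series$times)) {
    out[, , k] <- vorticity_field(series$mesh, series$velocity[, , k])$node
  }
  out
}

#' Helicity descriptors h1, h2, h3, h4 over a region and one cycle
#'
#' h1 is the cycle-and-volume-averaged helicity density v . omega (m/s^2), h2
#' the same with |v . omega| (helicity intensity), h3 = h1/h2 the signed
#' helical rotation balance in `[-1, 1]` (0 when h2 = 0 by convention) and
#' h4 = |h3| the unsigned balance. Volume integrals use per-cell midpoint
#' quadrature (arithmetic mean of the 4 nodal densities times cell volume);
#' time integrals are trapezoidal with wrap closure.
#'
#' @param series a [volume_series()].
#' @param vort vorticity array from [vorticity_series()]; computed if omitted.
#' @param region integer vector of cell indices, or an ROI name of the mesh;
#'   default all cells.
#' @param eps absolute floor on h2 (m/s^2) below which the flow is treated as
#'   helicity-free and h3 = h4 = 0 by convention, default 1e-12.
#' @return list of class `helicity_descriptors`: `h1`, `h2`, `h3`, `h4`.
#' @export
helicity_descriptors <- function(series, vort = NULL, region = NULL,
                                 eps = 1e-12) {
  stopifnot(inherits(series, "volume_series"))
  if (is.null(vort)) vort <- vorticity_series(series)
  if (!all(dim(vort) == dim(series$velocity))) stop("vorticity shape mismatch")
  mesh <- series$mesh
  if (is.null(region)) {
    region <- seq_len(nrow(mesh$cells))
  } else if (is.character(region)) {
    if (is.null(mesh$rois[[region]])) stop("unknown ROI: ", region)
    region <- mesh$rois[[region]]
  }
  if (!length(region)) stop("empty region")
  cells <- mesh$cells[region, , drop = FALSE]
  vol <- mesh$cell_volumes[region]
  V <- sum(vol)
  nt <- length(series$times)
  Hs <- numeric(nt)   # volume integral of v.omega per sample
  Ha <- numeric(nt)   # volume integral of |v.omega|
  for (k in seq_len(nt)) {
    dens <- rowSums(series$velocity[, , k] * vort[, , k])   # nodal v.omega
    cellmean <- (dens[cells[, 1]] + dens[cells[, 2]] +
                   dens[cells[, 3]] + dens[cells[, 4]]) / 4
    cellabs <- (abs(dens)[cells[, 1]] + abs(dens)[cells[, 2]] +
                  abs(dens)[cells[, 3]] + abs(dens)[cells[, 4]]) / 4
    Hs[k] <- sum(cellmean * vol)
    Ha[k] <- sum(cellabs * vol)
  }
  h1 <- cycle_mean(series$times, Hs, series$period) / V
  h2 <- cycle_mean(series$times, Ha, series$period) / V
  h3 <- if (h2 > eps) h1 / h2 else 0
  structure(list(h1 = h1, h2 = h2, h3 = h3, h4 = abs(h3)),
            class = "helicity_descriptors")
}

#' @export
print.helicity_descriptors <- function(x, ...) {
  cat(sprintf("h1 = %.4g m/s^2, h2 = %.4g m/s^2, h3 = %.3f, h4 = %.3f\n",
              x$h1, x$h2, x$h3, x$h4))
  invisible(x)
}

#' Local normalised helicity field
#'
#' LNH = v . omega / (|v| |omega|), the cosine of the angle between velocity
#' and vorticity, in `[-1, 1]`; set to 0 where |v||omega| < eps (irrotational
#' or stagnant points).
#'
#' @param velocity n x 3 matrix (m/s).
#' @param vorticity n x 3 matrix (1/s).
#' @param eps degeneracy floor on |v||omega| (SI), default 1e-12.
#' @return numeric vector of LNH per node.
#' @export
lnh_field <- function(velocity, vorticity, eps = 1e-12) {
  velocity <- as.matrix(velocity); vorticity <- as.matrix(vorticity)
  if (!all(dim(velocity) == dim(vorticity))) stop("shape mismatch")
  denom <- row_norms(velocity) * row_norms(vorticity)
  out <- ifelse(denom < eps, 0, rowSums(velocity * vorticity) / denom)
  pmin(1, pmax(-1, out))
}
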