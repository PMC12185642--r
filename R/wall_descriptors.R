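#' Time-averaged wall shear stress (TAWSS)
#'
#' (1/T) integral of |tau| dt per surface node, trapezoidal with wrap closure.
#'
#' @param series a [wss_series()].
#' @return numeric vector, TAWSS per node (Pa).
#' @export
tawss <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  mag <- apply(series$wss, 3, row_norms)      # n_nodes x n_times
  cycle_mean(series$times, t(mag), series$period)
}

#' Oscillatory shear index (OSI)
#'
#' OSI = 0.5 (1 - |int tau dt| / int |tau| dt) per node, in `[0, 0.5]`;
#' 0 where the cycle integral of |tau| is below `eps` (no shear at all).
#'
#' @param series a [wss_series()].
#' @param eps floor on int |tau| dt (Pa s), default 1e-9.
#' @return numeric vector, OSI per node.
#' @export
osi <- function(series, eps = 1e-9) {
  stopifnot(inherits(series, "wss_series"))
  w <- cycle_weights(series$times, series$period)
  nt <- length(series$times)
  n <- dim(series$wss)[1]
  vint <- matrix(0, n, 3)
  mint <- numeric(n)
  for (k in seq_len(nt)) {
    vint <- vint + w[k] * series$wss[, , k]
    mint <- mint + w[k] * row_norms(series$wss[, , k])
  }
  out <- ifelse(mint < eps, 0, 0.5 * (1 - row_norms(vint) / mint))
  pmin(0.5, pmax(0, out))
}

#' Transverse wall shear stress (transWSS)
#'
#' (1/T) integral of |tau . (n x m)| dt per node, where m is the unit vector
#' of the cycle-mean WSS and n the outward surface normal: the cycle-averaged
#' magnitude of the WSS component perpendicular to its own mean direction,
#' capturing multidirectional shear. Where the mean WSS vector is (near) zero
#' the mean direction m is undefined: those nodes get value 0 and are flagged.
#'
#' @param series a [wss_series()].
#' @param eps floor on |int tau dt| / T (Pa) below which a node is degenerate,
#'   default 1e-9.
#' @return list `value` (numeric per node, Pa) and `degenerate` (logical per
#'   node).
#' @export
transwss <- function(series, eps = 1e-9) {
  stopifnot(inherits(series, "wss_series"))
  w <- cycle_weights(series$times, series$period)
  nt <- length(series$times)
  n <- dim(series$wss)[1]
  vint <- matrix(0, n, 3)
  for (k in seq_len(nt)) vint <- vint + w[k] * series$wss[, , k]
  mmag <- row_norms(vint) / series$period
  degen <- mmag < eps
  m <- vint / pmax(row_norms(vint), .Machine$double.xmin)
  nxm <- cross3(series$mesh$normals, m)
  acc <- numeric(n)
  for (k in seq_len(nt)) {
    acc <- acc + w[k] * abs(rowSums(series$wss[, , k] * nxm))
  }
  val <- acc / series$period
  val[degen] <- 0
  list(value = val, degenerate = degen)
}

#' Surface divergence of the unit WSS vector field
#'
#' Normalises the WSS per node (u = tau/|tau|, zero where |tau| < eps) and
#' computes, per triangle, the in-plane divergence of the linearly
#' interpolated u: div u = sum_i u_i . grad phi_i with the shape-function
#' gradients lying in the triangle plane. Exact for fields affine within a
#' flat patch. Positive values mark expansion (backward saddle/source
#' behaviour of the near-wall flow), negative contraction.
#'
#' @param surface a [surface_mesh()].
#' @param tau n x 3 matrix of (tangential) WSS at one instant (Pa).
#' @param eps magnitude floor for normalisation (Pa), default 1e-6.
#' @return numeric vector, one divergence per triangle (1/m).
#' @export
unit_wss_divergence <- function(surface, tau, eps = 1e-6) {
  stopifnot(inherits(surface, "surface_mesh"))
  tau <- as.matrix(tau)
  mag <- row_norms(tau)
  u <- tau / pmax(mag, .Machine$double.xmin)
  u[mag < eps, ] <- 0
  tri <- surface$triangles
  p1 <- surface$nodes[tri[, 1], , drop = FALSE]
  p2 <- surface$nodes[tri[, 2], , drop = FALSE]
  p3 <- surface$nodes[tri[, 3], , drop = FALSE]
  nrm <- surface$tri_normals
  twoA <- 2 * surface$tri_areas
  g1 <- cross3(nrm, p3 - p2) / twoA
  g2 <- cross3(nrm, p1 - p3) / twoA
  g3 <- cross3(nrm, p2 - p1) / twoA
  rowSums(u[tri[, 1], , drop = FALSE] * g1) +
    rowSums(u[tri[, 2], , drop = FALSE] * g2) +
    rowSums(u[tri[, 3], , drop = FALSE] * g3)
}

#' Unit-WSS divergence time series
#'
#' @param series a [wss_series()].
#' @param eps magnitude floor passed to [unit_wss_divergence()].
#' @return matrix (n_triangles x n_times) of divergences (1/m).
#' @export
divergence_series <- function(series, eps = 1e-6) {
  stopifnot(inherits(series, "wss_series"))
  nt <- length(series$times)
  out <- matrix(0, nrow(series$mesh$triangles), nt)
  for (k in seq_len(nt)) {
    out[, k] <- unit_wss_divergence(series$mesh, series$wss[, , k], eps = eps)
  }
  out
}

#' Topological shear variation index (TSVI)
#'
#' Root-mean-square, over the cycle, of the unit-WSS divergence about its own
#' cycle mean: sqrt((1/T) int (D - Dbar)^2 dt) per triangle. Measures the
#' unsteadiness of the contraction/expansion pattern the WSS exerts on the
#' near-wall flow.
#'
#' @param div_series matrix (n_cells x n_times) from [divergence_series()].
#' @param times sample times (s).
#' @param period cycle period T (s).
#' @return numeric vector, TSVI per triangle (1/m).
#' @export
tsvi <- function(div_series, times, period) {
  div_series <- as.matrix(div_series)
  if (ncol(div_series) != length(times)) stop("time dimension mismatch")
  if (length(times) < 3L) stop("need at least 3 samples")
  dbar <- cycle_mean(times, t(div_series), period)
  dev2 <- (div_series - dbar)^2
  sqrt(pmax(cycle_mean(times, t(dev2), period), 0))
}

#' Area-weighted transfer of a per-cell field to nodes
#'
#' Used for reporting/thresholding cell-based quantities (divergence, TSVI)
#' on nodes: each node receives the area-weighted mean of its incident
#' triangles.
#'
#' @param surface a [surface_mesh()].
#' @param cell_values numeric vector per triangle.
#' @return numeric vector per node.
#' @export
cell_to_node <- function(surface, cell_values) {
  stopifnot(inherits(surface, "surface_mesh"))
  tri <- surface$triangles
  num <- numeric(nrow(surface$nodes))
  den <- numeric(nrow(surface$nodes))
  for (k in 1:3) {
    acc <- rowsum(cbind(cell_values * surface$tri_areas, surface$tri_areas),
                  tri[, k])
    idx <- as.integer(rownames(acc))
    num[idx] <- num[idx] + acc[, 1]
    den[idx] <- den[idx] + acc[, 2]
  }
  num / pmax(den, .Machine$double.xmin)
}

#' All wall descriptors of a WSS series
#'
#' Convenience wrapper computing TAWSS, OSI, transWSS (per node) and the
#' divergence series and TSVI (per cell).
#'
#' @param series a [wss_series()].
#' @return list of class `wall_descriptor_set`: `tawss`, `osi`, `transwss`,
#'   `transwss_degenerate`, `divergence` (cells x times), `tsvi` (per cell),
#'   `tsvi_node` (area-weighted node transfer).
#' @export
wall_descriptors <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  tw <- transwss(series)
  dv <- divergence_series(series)
  ts <- tsvi(dv, series$times, series$period)
  structure(list(tawss = tawss(series), osi = osi(series),
                 transwss = tw$value, transwss_degenerate = tw$degenerate,
                 divergence = dv, tsvi = ts,
                 tsvi_node = cell_to_node(series$mesh, ts)),
            class = "wall_descriptor_set")
}
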