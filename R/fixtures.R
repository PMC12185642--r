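#' Structured tetrahedral cylinder mesh with wall surface
#'
#' Builds a deterministic structured mesh of a circular pipe of radius `R`
#' and length `length`: a disk triangulation (centre fan plus quad rings,
#' quads split by the smaller-index diagonal) extruded along z into prisms,
#' each prism split into 3 tetrahedra with the index-based diagonal rule so
#' shared faces agree between neighbours (conforming mesh). The lateral wall
#' is returned as a [surface_mesh()] with outward radial normals.
#'
#' @param R radius (m).
#' @param length axial length (m).
#' @param n_circ circumferential node count (>= 6).
#' @param n_rad radial ring count (>= 2).
#' @param n_axial axial layer count (>= 2).
#' @return list `volume` ([volume_mesh()]), `wall` ([surface_mesh()]),
#'   `wall_node_ids` (volume node index per wall node).
#' @export
make_cylinder_mesh <- function(R = 0.003, length = 0.02, n_circ = 16L,
                               n_rad = 4L, n_axial = 10L) {
  if (R <= 0 || length <= 0) stop("R and length must be positive")
  if (n_circ < 6L || n_rad < 2L || n_axial < 2L) {
    stop("resolution too coarse: need n_circ >= 6, n_rad >= 2, n_axial >= 2")
  }
  nc <- as.integer(n_circ); nr <- as.integer(n_rad); nz <- as.integer(n_axial)
  ang <- 2 * pi * (seq_len(nc) - 1) / nc
  # disk nodes: centre then rings 1..nr (radius j R / nr)
  disk <- rbind(c(0, 0),
                do.call(rbind, lapply(seq_len(nr), function(j) {
                  r <- j * R / nr
                  cbind(r * cos(ang), r * sin(ang))
                })))
  nd <- nrow(disk)                       # 1 + nr*nc
  did <- function(j, i) {                # ring j (>=1), slot i (0-based, wrapped)
    1L + (j - 1L) * nc + (i %% nc) + 1L
  }
  # disk triangles
  tris <- vector("list", 0L)
  for (i in 0:(nc - 1L)) tris[[length(tris) + 1L]] <- c(1L, did(1, i), did(1, i + 1))
  for (j in seq_len(nr - 1L)) {
    for (i in 0:(nc - 1L)) {
      a <- did(j, i); b <- did(j, i + 1); cc <- did(j + 1, i + 1); d <- did(j + 1, i)
      # quad (a,b,cc,d): diagonal through the smallest index
      if (min(a, cc) < min(b, d)) {
        tris[[length(tris) + 1L]] <- c(a, b, cc)
        tris[[length(tris) + 1L]] <- c(a, cc, d)
      } else {
        tris[[length(tris) + 1L]] <- c(a, b, d)
        tris[[length(tris) + 1L]] <- c(b, cc, d)
      }
    }
  }
  tris <- do.call(rbind, tris)
  zs <- length * (0:nz) / nz
  nodes <- do.call(rbind, lapply(zs, function(z) cbind(disk, z)))
  # prisms between layers, split into tets
  cells <- matrix(0L, nrow(tris) * nz * 3L, 4L)
  ct <- 0L
  for (k in 0:(nz - 1L)) {
    off_b <- k * nd; off_t <- (k + 1L) * nd
    for (q in seq_len(nrow(tris))) {
      w <- c(tris[q, ] + off_b, tris[q, ] + off_t)
      tets <- split_prism(w)
      cells[ct + 1:3, ] <- tets
      ct <- ct + 3L
    }
  }
  vol <- volume_mesh(nodes, cells)
  # lateral wall: outer-ring nodes of every layer
  wall_ids <- as.vector(vapply(0:nz, function(k) {
    k * nd + (1L + (nr - 1L) * nc + seq_len(nc))
  }, integer(nc)))
  remap <- integer(nrow(nodes)); remap[wall_ids] <- seq_along(wall_ids)
  wid <- function(k, i) remap[k * nd + 1L + (nr - 1L) * nc + (i %% nc) + 1L]
  wt <- vector("list", 0L)
  for (k in 0:(nz - 1L)) {
    for (i in 0:(nc - 1L)) {
      a <- wid(k, i); b <- wid(k, i + 1); cc <- wid(k + 1, i + 1); d <- wid(k + 1, i)
      ga <- wall_ids[a]; gb <- wall_ids[b]; gc <- wall_ids[cc]; gd <- wall_ids[d]
      if (min(ga, gc) < min(gb, gd)) {
        wt[[length(wt) + 1L]] <- c(a, b, cc); wt[[length(wt) + 1L]] <- c(a, cc, d)
      } else {
        wt[[length(wt) + 1L]] <- c(a, b, d); wt[[length(wt) + 1L]] <- c(b, cc, d)
      }
    }
  }
  wt <- do.call(rbind, wt)
  wnodes <- nodes[wall_ids, , drop = FALSE]
  # wind triangles so normals point radially outward
  for (q in seq_len(nrow(wt))) {
    p <- wnodes[wt[q, ], , drop = FALSE]
    nrm <- c(crossv(p[2, ] - p[1, ], p[3, ] - p[1, ]))
    cen <- colMeans(p)
    if (sum(nrm * c(cen[1], cen[2], 0)) < 0) wt[q, ] <- wt[q, c(1L, 3L, 2L)]
  }
  # exact analytic outward normals of the cylinder wall
  wn <- cbind(wnodes[, 1], wnodes[, 2], 0)
  wn <- wn / row_norms(wn)
  wall <- surface_mesh(wnodes, wt, normals = wn)
  list(volume = vol, wall = wall, wall_node_ids = wall_ids)
}

#' @keywords internal
crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @keywords internal
split_prism <- function(w) {
  # w: 6 global node ids, bottom (1:3), top (4:6), w[i+3] above w[i].
  # Index-based (smallest-vertex) diagonal rule: conforming across prisms.
  imin <- which.min(w)
  if (imin > 3L) w <- w[c(4:6, 1:3)]       # flip so the smallest is on bottom
  imin <- which.min(w[1:3])
  rot <- ((imin - 1L + 0:2) %% 3L) + 1L    # rotate smallest to position 1
  w <- w[c(rot, rot + 3L)]
  v0 <- w[1]; v1 <- w[2]; v2 <- w[3]; v3 <- w[4]; v4 <- w[5]; v5 <- w[6]
  if (min(v1, v5) < min(v2, v4)) {
    rbind(c(v0, v1, v2, v5), c(v0, v1, v5, v4), c(v0, v4, v5, v3))
  } else {
    rbind(c(v0, v1, v2, v4), c(v0, v4, v2, v5), c(v0, v4, v5, v3))
  }
}

#' Flat triangulated annulus in the z = 0 plane
#'
#' Oracle surface for the unit-WSS divergence: a radial unit field on this
#' annulus has analytic surface divergence 1/r. Normals point along +z.
#'
#' @param r_in,r_out inner/outer radii (m), `0 < r_in < r_out`.
#' @param n_rad radial intervals; `n_circ` circumferential nodes.
#' @param n_circ circumferential node count.
#' @return a [surface_mesh()].
#' @export
make_annulus_surface <- function(r_in, r_out, n_rad = 8L, n_circ = 32L) {
  if (r_in <= 0 || r_out <= r_in) stop("need 0 < r_in < r_out")
  nc <- as.integer(n_circ); nr <- as.integer(n_rad)
  ang <- 2 * pi * (seq_len(nc) - 1) / nc
  radii <- r_in + (r_out - r_in) * (0:nr) / nr
  nodes <- do.call(rbind, lapply(radii, function(r) {
    cbind(r * cos(ang), r * sin(ang), 0)
  }))
  id <- function(j, i) j * nc + (i %% nc) + 1L      # j = 0..nr
  tris <- vector("list", 0L)
  for (j in 0:(nr - 1L)) {
    for (i in 0:(nc - 1L)) {
      a <- id(j, i); b <- id(j, i + 1); cc <- id(j + 1, i + 1); d <- id(j + 1, i)
      if (min(a, cc) < min(b, d)) {
        tris[[length(tris) + 1L]] <- c(a, b, cc); tris[[length(tris) + 1L]] <- c(a, cc, d)
      } else {
        tris[[length(tris) + 1L]] <- c(a, b, d); tris[[length(tris) + 1L]] <- c(b, cc, d)
      }
    }
  }
  tris <- do.call(rbind, tris)
  # wind for +z normals
  for (q in seq_len(nrow(tris))) {
    p <- nodes[tris[q, ], , drop = FALSE]
    if (crossv(p[2, ] - p[1, ], p[3, ] - p[1, ])[3] < 0) {
      tris[q, ] <- tris[q, c(1L, 3L, 2L)]
    }
  }
  surface_mesh(nodes, tris, normals = matrix(rep(c(0, 0, 1), each = nrow(nodes)),
                                             ncol = 3))
}

# --- analytic flow generators ----------------------------------------------

#' @keywords internal
besselJ01_complex <- function(z, nu) {
  # power series; accurate for |z| up to ~20 in double precision
  term <- (z / 2)^nu / gamma(nu + 1)
  s <- term
  for (m in 1:200) {
    term <- term * (-(z / 2)^2) / (m * (m + nu))
    s <- s + term
    if (all(Mod(term) < 1e-18 * (Mod(s) + 1e-300)) && m > 5) break
  }
  s
}

#' Womersley pulsatile pipe-flow evaluators
#'
#' Analytic fully developed axisymmetric pipe flow driven by a flow waveform
#' Q(t) = Q0 + sum_n Re(Q_n exp(i n omega t)). The steady component is
#' Poiseuille; each harmonic uses the classical Womersley profile scaled so
#' its cross-sectional integral equals the prescribed flow harmonic. Wall
#' shear is the analytic radial derivative at r = R. Requires constant
#' viscosity (the Womersley solution is Newtonian). Accurate for Womersley
#' numbers up to about 20 (power-series Bessel evaluation).
#'
#' @param R pipe radius (m).
#' @param Q0 steady flow component (m^3/s).
#' @param Qn complex vector of flow harmonics 1..N (m^3/s); may be empty.
#' @param mu dynamic viscosity (Pa s).
#' @param rho density (kg/m^3).
#' @param omega fundamental angular frequency (rad/s).
#' @return list of class `womersley_field`: `velocity(r, t)` axial velocity
#'   (m/s), `wss(t)` wall shear magnitude history (Pa, positive for forward
#'   flow), `flow(t)`, `alpha` (Womersley numbers per harmonic), and the
#'   parameters.
#' @export
womersley_field <- function(R, Q0, Qn = complex(0), mu, rho, omega) {
  if (R <= 0 || mu <= 0 || rho <= 0 || omega <= 0) {
    stop("R, mu, rho, omega must be positive")
  }
  Qn <- as.complex(Qn)
  N <- length(Qn)
  i32 <- exp(1i * 3 * pi / 4)              # i^(3/2)
  alpha <- if (N) R * sqrt((1:N) * omega * rho / mu) else numeric(0)
  Lam <- i32 * alpha
  J0L <- if (N) besselJ01_complex(Lam, 0) else complex(0)
  J1L <- if (N) besselJ01_complex(Lam, 1) else complex(0)
  D <- if (N) 1 - 2 * J1L / (Lam * J0L) else complex(0)
  velocity <- function(r, t) {
    u <- 2 * Q0 / (pi * R^2) * (1 - (r / R)^2)
    for (n in seq_len(N)) {
      prof <- (1 - besselJ01_complex(Lam[n] * r / R, 0) / J0L[n]) / D[n]
      u <- u + Re(Qn[n] / (pi * R^2) * prof * exp(1i * n * omega * t))
    }
    u
  }
  wss <- function(t) {
    tau <- rep(4 * mu * Q0 / (pi * R^3), length(t))
    for (n in seq_len(N)) {
      coef <- -mu * Qn[n] / (pi * R^2 * D[n]) * (Lam[n] / R) * J1L[n] / J0L[n]
      tau <- tau + Re(coef * exp(1i * n * omega * t))
    }
    tau
  }
  flow <- function(t) {
    q <- rep(Q0, length(t))
    for (n in seq_len(N)) q <- q + Re(Qn[n] * exp(1i * n * omega * t))
    q
  }
  structure(list(velocity = velocity, wss = wss, flow = flow, alpha = alpha,
                 R = R, Q0 = Q0, Qn = Qn, mu = mu, rho = rho, omega = omega),
            class = "womersley_field")
}

#' Rigid-rotation helical velocity field
#'
#' v = (-Omega y, Omega x, W): solid-body rotation about z plus axial drift.
#' Closed forms: vorticity (0, 0, 2 Omega), helicity density 2 Omega W
#' everywhere, LNH(r) = W / sqrt(Omega^2 r^2 + W^2).
#'
#' @param Omega rotation rate (1/s).
#' @param W axial drift (m/s).
#' @return function(nodes) -> n x 3 velocity matrix, with attribute
#'   `expected` carrying the closed forms.
#' @export
helical_field <- function(Omega, W) {
  f <- function(nodes) {
    nodes <- as.matrix(nodes)
    cbind(-Omega * nodes[, 2], Omega * nodes[, 1], rep(W, nrow(nodes)))
  }
  attr(f, "expected") <- list(
    vorticity = c(0, 0, 2 * Omega),
    helicity_density = 2 * Omega * W,
    h1 = 2 * Omega * W, h2 = abs(2 * Omega * W),
    h4 = if (Omega * W != 0) 1 else 0,
    lnh = function(r) W / sqrt(Omega^2 * r^2 + W^2))
  f
}

#' Prescribed spatio-temporal WSS patterns with closed-form descriptors
#'
#' Generates a [wss_series()] on any surface from a named analytic pattern,
#' expressed in the local tangent basis (e1 = tangential projection of a
#' reference direction, e2 = n x e1):
#' \describe{
#'   \item{unidirectional_pulsatile}{tau = (tau0 + tau1 sin(2 pi t/T)) e1;
#'     TAWSS = tau0 (for tau0 > tau1 >= 0), OSI = 0, transWSS = 0.}
#'   \item{reversing}{+tau0 e1 for the first half cycle, -tau0 e1 after;
#'     TAWSS = tau0, OSI = 0.5, transWSS degenerate (mean WSS = 0).}
#'   \item{rotating}{tau0 (cos(2 pi t/T) e1 + sin(2 pi t/T) e2); TAWSS = tau0.}
#'   \item{biaxial}{tau0 e1 + tau1 sin(2 pi t/T) e2; transWSS =
#'     (1/T) int |tau . (n x m)| dt with m the exact mean direction.}
#'   \item{divergence_switching}{+tau0 r-hat for the first half cycle,
#'     -tau0 r-hat after (r-hat = in-plane radial direction); the unit-WSS
#'     divergence alternates +/- 1/r, so TSVI = 1/r at radius r and the
#'     cycle-mean divergence is 0.}
#' }
#'
#' @param surface a [surface_mesh()].
#' @param kind pattern name (above).
#' @param tau0,tau1 magnitudes (Pa).
#' @param period cycle T (s).
#' @param n_samples samples per cycle (even; no wrap sample), default 32.
#' @param ref_dir reference direction for e1, default c(0, 0, 1).
#' @return a [wss_series()] with attribute `expected` (closed forms).
#' @export
synthetic_wss_pattern <- function(surface, kind, tau0 = 1, tau1 = 0.5,
                                  period = 0.8, n_samples = 32L,
                                  ref_dir = c(0, 0, 1)) {
  stopifnot(inherits(surface, "surface_mesh"))
  kinds <- c("unidirectional_pulsatile", "reversing", "rotating", "biaxial",
             "divergence_switching")
  if (!kind %in% kinds) {
    stop("unknown pattern kind: ", kind, " (use one of ",
         paste(kinds, collapse = ", "), ")")
  }
  n_samples <- as.integer(n_samples)
  if (n_samples %% 2L != 0L) stop("n_samples must be even")
  nn <- surface$normals
  n_pts <- nrow(nn)
  d <- matrix(rep(ref_dir / sqrt(sum(ref_dir^2)), each = n_pts), ncol = 3)
  e1 <- d - nn * rowSums(d * nn)
  bad <- row_norms(e1) < 1e-8
  if (any(bad)) {                          # fall back where ref_dir ~ normal
    d2 <- matrix(rep(c(1, 0, 0), each = n_pts), ncol = 3)
    alt <- d2 - nn * rowSums(d2 * nn)
    e1[bad, ] <- alt[bad, ]
  }
  e1 <- e1 / row_norms(e1)
  e2 <- cross3(nn, e1)
  times <- period * (seq_len(n_samples) - 1) / n_samples
  arr <- array(0, c(n_pts, 3, n_samples))
  expected <- list(kind = kind, tau0 = tau0, tau1 = tau1)
  if (kind == "divergence_switching") {
    rad <- cbind(surface$nodes[, 1], surface$nodes[, 2], 0)
    r <- row_norms(rad)
    if (any(r < 1e-12)) stop("divergence_switching needs nodes off the axis")
    rhat <- rad / r
    rhat <- rhat - nn * rowSums(rhat * nn)   # keep tangential on curved walls
    rhat <- rhat / pmax(row_norms(rhat), .Machine$double.xmin)
    for (k in seq_len(n_samples)) {
      s <- if (times[k] < period / 2) 1 else -1
      arr[, , k] <- s * tau0 * rhat
    }
    expected$tsvi_at_radius <- function(r) 1 / r
    expected$mean_divergence <- 0
  } else {
    for (k in seq_len(n_samples)) {
      ph <- 2 * pi * times[k] / period
      tau_k <- switch(kind,
        unidirectional_pulsatile = (tau0 + tau1 * sin(ph)) * e1,
        reversing = (if (times[k] < period / 2) tau0 else -tau0) * e1,
        rotating = tau0 * (cos(ph) * e1 + sin(ph) * e2),
        biaxial = tau0 * e1 + tau1 * sin(ph) * e2)
      arr[, , k] <- tau_k
    }
    expected <- c(expected, switch(kind,
      unidirectional_pulsatile = list(tawss = tau0, osi = 0, transwss = 0),
      reversing = list(tawss = tau0, osi = 0.5, transwss_degenerate = TRUE),
      rotating = list(tawss = tau0),
      biaxial = list()))
  }
  out <- wss_series(surface, times, arr, period)
  attr(out, "expected") <- expected
  out
}

#' Carreau-Yasuda rheology parameters
#'
#' Shear-thinning blood viscosity parameters. Defaults are the classical
#' Carreau-Yasuda blood values (zero-shear 0.056 Pa s, infinite-shear
#' 0.00345 Pa s, relaxation 3.313 s, Yasuda exponent 2, power index 0.3568);
#' all are configuration-overridable.
#'
#' @param mu0 zero-shear viscosity (Pa s).
#' @param mu_inf infinite-shear viscosity (Pa s), `0 < mu_inf <= mu0`.
#' @param lambda relaxation time (s), positive.
#' @param a Yasuda exponent, positive.
#' @param n power index in (0, 1].
#' @return object of class `rheology_params`.
#' @export
rheology_params <- function(mu0 = 0.056, mu_inf = 0.00345, lambda = 3.313,
                            a = 2, n = 0.3568) {
  if (mu_inf <= 0 || mu0 < mu_inf) stop("need mu0 >= mu_inf > 0")
  if (lambda <= 0 || a <= 0) stop("lambda and a must be positive")
  if (n <= 0 || n > 1) stop("n must be in (0, 1]")
  structure(list(mu0 = mu0, mu_inf = mu_inf, lambda = lambda, a = a, n = n),
            class = "rheology_params")
}

#' Carreau-Yasuda viscosity evaluator
#'
#' mu(gamma) = mu_inf + (mu0 - mu_inf) (1 + (lambda gamma)^a)^((n - 1)/a).
#'
#' @param gamma_dot shear rate (1/s), non-negative (vectorised).
#' @param params a [rheology_params()].
#' @return viscosity (Pa s).
#' @export
carreau_yasuda_viscosity <- function(gamma_dot, params = rheology_params()) {
  stopifnot(inherits(params, "rheology_params"))
  if (any(gamma_dot < 0)) stop("shear rate must be non-negative")
  params$mu_inf + (params$mu0 - params$mu_inf) *
    (1 + (params$lambda * gamma_dot)^params$a)^((params$n - 1) / params$a)
}

#' Toy six-segment AVG lumped-parameter network
#'
#' Synthetic 0D twin of a brachiocephalic closed-loop AVG domain: one inflow
#' (brachial artery, the inlet segment absorbing the anastomosis section),
#' three WK3-terminated arterial outlet branches whose different segment
#' coefficients (from their cross-sectional areas) set the inter-outlet flow
#' split, an arterial-plus-venous side graft segment, and a venous
#' restriction draining into a fixed venous pressure sink (8 mmHg central
#' venous pressure). Segment inertances follow L = (4/3) rho l / A; quadratic
#' resistance coefficients are plausible fitted values for graft-calibre
#' vessels at AVG flow rates (about 1 L/min). The placeholder WK3 values are
#' physiological but uncalibrated; [calibrate_wk3()] tunes them.
#'
#' @param rho blood density (kg/m^3), default 1056.
#' @param venous_pressure sink pressure (Pa), default `mmHg_to_Pa(8)`.
#' @return a [network0d()].
#' @export
toy_avg_network <- function(rho = 1056, venous_pressure = mmHg_to_Pa(8)) {
  seg <- data.frame(
    name = c("inlet", "ao1_branch", "ao2_branch", "ao3_branch",
             "graft", "venous_restriction"),
    from = c("inlet", "anast", "anast", "anast", "anast", "vrestr"),
    to = c("anast", "ao1", "ao2", "ao3", "vrestr", "vout"),
    a = c(2e11, 1e12, 1.5e12, 2e12, 3e12, 5e12),
    b = c(1.0e8, 5e7, 8e7, 1.2e8, 4.5e8, 3e8),
    l = c(0.12, 0.03, 0.03, 0.03, 0.35, 0.05),
    A = c(2.2e-5, 7e-6, 5e-6, 3.5e-6, 2.4e-5, 1.2e-5),
    stringsAsFactors = FALSE)
  seg$L <- segment_inertance(seg$l, seg$A, rho)
  network0d(
    nodes = c("inlet", "anast", "ao1", "ao2", "ao3", "vrestr", "vout"),
    segments = seg,
    terminations = list(
      inlet = inflow_marker(),
      ao1 = wk3_params(2.9e9, 4.4e9, 2e-10),
      ao2 = wk3_params(2.9e9, 4.4e9, 2e-10),
      ao3 = wk3_params(2.9e9, 4.4e9, 2e-10),
      vout = pressure_sink(venous_pressure)))
}

#' Parametric pulsatile AVG inflow waveform
#'
#' Two-harmonic positive pulse typical of brachial inflow to a dialysis
#' access: Q(t) = Qm (1 + 0.6 sin(2 pi t/T) + 0.2 sin(4 pi t/T - pi/2)),
#' cycle mean Qm, no retrograde flow.
#'
#' @param q_mean cycle-mean flow (m^3/s), default 1.5e-5 (0.9 L/min).
#' @param period cardiac period (s), default 0.8.
#' @param n_samples samples per cycle, default 64.
#' @return a periodic [waveform()] in m^3/s.
#' @export
toy_inflow_waveform <- function(q_mean = 1.5e-5, period = 0.8,
                                n_samples = 64L) {
  t <- period * (seq_len(n_samples) - 1) / n_samples
  q <- q_mean * (1 + 0.6 * sin(2 * pi * t / period) +
                   0.2 * sin(4 * pi * t / period - pi / 2))
  waveform(t, q, period, units = "m3/s", periodic = TRUE)
}

#' Partition a surface into axial ROIs by centroid z
#'
#' @param surface a [surface_mesh()].
#' @param breaks named list of c(zmin, zmax) intervals (half-open
#'   `[zmin, zmax)` except the last, which is closed).
#' @return the surface with `rois` set (named triangle-index lists).
#' @export
axial_rois <- function(surface, breaks) {
  stopifnot(inherits(surface, "surface_mesh"))
  z <- surface$tri_centroids[, 3]
  rois <- lapply(seq_along(breaks), function(i) {
    b <- breaks[[i]]
    if (i == length(breaks)) which(z >= b[1] & z <= b[2])
    else which(z >= b[1] & z < b[2])
  })
  names(rois) <- names(breaks)
  surface$rois <- rois
  surface
}
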