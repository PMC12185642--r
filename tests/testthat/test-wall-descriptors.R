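test_that("TAWSS: constant magnitude histories and the Poiseuille value", {
  patch <- flat_patch()
  T_ <- 0.8
  t16 <- T_ * (0:15) / 16
  # fixed direction, |tau| = 2
  s1 <- patch_series(patch, t16, T_, function(t) {
    matrix(rep(c(2, 0, 0), each = 4), ncol = 3)
  })
  expect_equal(tawss(s1), rep(2, 4), tolerance = 1e-12)
  # rotating in the tangent plane, constant modulus tau0
  s2 <- patch_series(patch, t16, T_, function(t) {
    ph <- 2 * pi * t / T_
    matrix(rep(c(1.5 * cos(ph), 1.5 * sin(ph), 0), each = 4), ncol = 3)
  })
  expect_equal(tawss(s2), rep(1.5, 4), tolerance = 1e-12)

  # steady Poiseuille on the refined cylinder wall: TAWSS = 4 mu Q / (pi R^3)
  cyl <- refined_cylinder()
  mu <- 0.0035; R <- 0.003; Q0 <- 1e-5
  wf <- womersley_field(R, Q0, mu = mu, rho = 1056, omega = 2 * pi / T_)
  axial <- matrix(rep(c(0, 0, -1), each = nrow(cyl$wall$nodes)), ncol = 3)
  s3 <- patch_series(cyl$wall, t16, T_, function(t) wf$wss(t) * axial)
  expect_lt(max(abs(tawss(s3) - 4 * mu * Q0 / (pi * R^3))),
            0.02 * 4 * mu * Q0 / (pi * R^3))
})

test_that("OSI: 0 for any fixed-direction history, 0.5 for perfect reversal", {
  patch <- flat_patch()
  T_ <- 1
  t16 <- T_ * (0:15) / 16
  s_uni <- patch_series(patch, t16, T_, function(t) {
    matrix(rep(c(1 + 0.5 * sin(2 * pi * t / T_), 0, 0), each = 4), ncol = 3)
  })
  expect_equal(osi(s_uni), rep(0, 4), tolerance = 1e-12)

  s_rev <- synthetic_wss_pattern(patch, "reversing", tau0 = 1, period = T_,
                                 n_samples = 16L, ref_dir = c(1, 0, 0))
  expect_equal(osi(s_rev), rep(0.5, 4), tolerance = 1e-12)

  # all-zero shear: OSI 0 by the eps convention
  s_zero <- patch_series(patch, t16, T_, function(t) matrix(0, 4, 3))
  expect_equal(osi(s_zero), rep(0, 4))
})

test_that("transWSS: zero for unidirectional, dense-quadrature oracle for biaxial", {
  patch <- flat_patch()
  T_ <- 0.8
  t512 <- T_ * (0:511) / 512
  s_uni <- patch_series(patch, t512, T_, function(t) {
    matrix(rep(c(2 + sin(2 * pi * t / T_), 0, 0), each = 4), ncol = 3)
  })
  tw <- transwss(s_uni)
  expect_lt(max(tw$value), 1e-12)
  expect_false(any(tw$degenerate))

  tau0 <- 1; tau1 <- 0.5
  s_bi <- synthetic_wss_pattern(patch, "biaxial", tau0 = tau0, tau1 = tau1,
                                period = T_, n_samples = 512L)
  twb <- transwss(s_bi)
  # independent dense-quadrature oracle on the analytic pattern (10x time
  # resolution): mean direction from the dense integral, then the transverse
  # projection integral
  td <- T_ * (0:5119) / 5120
  tau_e1 <- rep(tau0, length(td))
  tau_e2 <- tau1 * sin(2 * pi * td / T_)
  m <- c(mean(tau_e1), mean(tau_e2))
  m <- m / sqrt(sum(m^2))
  perp <- c(-m[2], m[1])
  oracle <- mean(abs(tau_e1 * perp[1] + tau_e2 * perp[2]))
  expect_lt(max(abs(twb$value - oracle)), 0.001 * oracle)

  # perfect reversal: mean WSS ~ 0, degenerate convention
  s_rev <- synthetic_wss_pattern(patch, "reversing", tau0 = 1, period = T_,
                                 n_samples = 16L, ref_dir = c(1, 0, 0))
  twr <- transwss(s_rev)
  expect_true(all(twr$degenerate))
  expect_equal(twr$value, rep(0, 4))
})

test_that("unit-WSS divergence: uniform field, radial 1/r, sign flip", {
  patch <- flat_patch()
  u_uni <- matrix(rep(c(1, 0, 0), each = 4), ncol = 3)
  expect_lt(max(abs(unit_wss_divergence(patch, u_uni))), 1e-12)

  ann <- make_annulus_surface(0.001, 0.003, n_rad = 32L, n_circ = 128L)
  rad <- cbind(ann$nodes[, 1], ann$nodes[, 2], 0)
  rhat <- rad / sqrt(rowSums(rad^2))
  dv <- unit_wss_divergence(ann, rhat)
  rc <- sqrt(ann$tri_centroids[, 1]^2 + ann$tri_centroids[, 2]^2)
  expect_lt(max(abs(dv - 1 / rc) * rc), 0.03)
  expect_equal(unit_wss_divergence(ann, -rhat), -dv, tolerance = 1e-12)
})

test_that("divergence error decreases monotonically under mesh refinement", {
  err <- vapply(c(8L, 16L, 32L), function(nr) {
    ann <- make_annulus_surface(0.001, 0.003, n_rad = nr, n_circ = 4L * nr)
    rad <- cbind(ann$nodes[, 1], ann$nodes[, 2], 0)
    rhat <- rad / sqrt(rowSums(rad^2))
    dv <- unit_wss_divergence(ann, rhat)
    rc <- sqrt(ann$tri_centroids[, 1]^2 + ann$tri_centroids[, 2]^2)
    max(abs(dv - 1 / rc) * rc)
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("TSVI: constant divergence gives 0, alternating +/-d gives d, homogeneity", {
  T_ <- 1
  t8 <- T_ * (0:7) / 8
  const <- matrix(2.5, 10, 8)
  expect_equal(tsvi(const, t8, T_), rep(0, 10), tolerance = 1e-12)
  alt <- matrix(rep(c(3, 3, 3, 3, -3, -3, -3, -3), each = 5), 5)
  expect_equal(tsvi(alt, t8, T_), rep(3, 5), tolerance = 1e-12)
  rnd <- matrix(rnorm(40), 5)
  expect_equal(tsvi(4 * rnd, t8, T_), 4 * tsvi(rnd, t8, T_), tolerance = 1e-12)
})

test_that("OSI and transWSS bounds hold on random tangential fields", {
  patch <- flat_patch()
  T_ <- 1
  t12 <- T_ * (0:11) / 12
  set.seed(42)
  for (rep_i in 1:20) {
    arr <- array(0, c(4, 3, 12))
    arr[, 1, ] <- rnorm(48)
    arr[, 2, ] <- rnorm(48)
    s <- wss_series(patch, t12, arr, T_)
    o <- osi(s)
    expect_true(all(o >= 0 & o <= 0.5))
    tw <- transwss(s)
    ta <- tawss(s)
    expect_true(all(tw$value <= ta + 1e-12))
  }
})

test_that("all four indices are invariant under rigid rotation of the dataset", {
  cyl <- coarse_cylinder()
  T_ <- 0.8
  s <- synthetic_wss_pattern(cyl$wall, "biaxial", tau0 = 1.2, tau1 = 0.6,
                             period = T_, n_samples = 16L)
  d0 <- wall_descriptors(s)
  th <- 0.7; ax <- c(1, 2, 2) / 3
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  mesh_r <- surface_mesh(cyl$wall$nodes %*% t(R), cyl$wall$triangles,
                         normals = cyl$wall$normals %*% t(R))
  arr_r <- s$wss
  for (k in seq_along(s$times)) arr_r[, , k] <- s$wss[, , k] %*% t(R)
  s_r <- wss_series(mesh_r, s$times, arr_r, T_)
  d1 <- wall_descriptors(s_r)
  expect_equal(d1$tawss, d0$tawss, tolerance = 1e-9)
  expect_equal(d1$osi, d0$osi, tolerance = 1e-9)
  expect_equal(d1$transwss, d0$transwss, tolerance = 1e-9)
  expect_equal(d1$tsvi, d0$tsvi, tolerance = 1e-6)
})

test_that("trapezoidal cycle integration matches a 10x-oversampled oracle", {
  patch <- flat_patch()
  T_ <- 0.8
  f <- function(t) {
    ph <- 2 * pi * t / T_
    matrix(rep(c(1 + 0.4 * cos(ph), 0.5 * sin(ph) + 0.2 * sin(2 * ph), 0),
               each = 4), ncol = 3)
  }
  s <- patch_series(patch, T_ * (0:63) / 64, T_, f)
  s10 <- patch_series(patch, T_ * (0:639) / 640, T_, f)
  expect_lt(max(abs(tawss(s) - tawss(s10))), 0.001 * max(tawss(s10)))
  expect_lt(max(abs(transwss(s)$value - transwss(s10)$value)),
            0.001 * max(transwss(s10)$value))
})

test_that("loaded WSS is projected tangential and the deviation recorded", {
  patch <- flat_patch()
  T_ <- 1
  t4 <- T_ * (0:3) / 4
  arr <- array(0, c(4, 3, 4))
  arr[, 1, ] <- 1
  arr[, 3, ] <- 0.25          # normal contamination
  s <- wss_series(patch, t4, arr, T_)
  expect_equal(s$max_normal_deviation, 0.25)
  for (k in 1:4) {
    expect_lt(max(abs(rowSums(s$wss[, , k] * patch$normals))), 1e-12)
  }
})
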