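test_that("cylinder mesh: conforming, outward normals, analytic area and volume", {
  cyl <- refined_cylinder()
  R <- 0.003; L <- 0.02
  # every interior triangular face is shared by exactly 2 tets (conformity)
  cells <- cyl$volume$cells
  faces <- rbind(cells[, c(1, 2, 3)], cells[, c(1, 2, 4)],
                 cells[, c(1, 3, 4)], cells[, c(2, 3, 4)])
  faces <- t(apply(faces, 1, sort))
  counts <- table(paste(faces[, 1], faces[, 2], faces[, 3]))
  expect_true(all(counts %in% c(1L, 2L)))
  expect_true(all(cyl$volume$cell_volumes > 0))
  # analytic lateral area and volume within 1% at the refined setting
  expect_rel_equal(sum(cyl$wall$tri_areas), 2 * pi * R * L, 0.01)
  expect_rel_equal(sum(cyl$volume$cell_volumes), pi * R^2 * L, 0.01)
  # every wall normal has positive outward radial component
  rad <- cbind(cyl$wall$nodes[, 1], cyl$wall$nodes[, 2], 0)
  rad <- rad / sqrt(rowSums(rad^2))
  expect_true(all(rowSums(cyl$wall$normals * rad) > 0))
  expect_error(make_cylinder_mesh(n_circ = 4), "too coarse")
})

test_that("cylinder meshing is deterministic", {
  a <- make_cylinder_mesh(n_circ = 12, n_rad = 3, n_axial = 5)
  b <- make_cylinder_mesh(n_circ = 12, n_rad = 3, n_axial = 5)
  expect_identical(a$volume$nodes, b$volume$nodes)
  expect_identical(a$volume$cells, b$volume$cells)
  expect_identical(a$wall$triangles, b$wall$triangles)
})

test_that("complex Bessel series agrees with base besselJ on the real axis", {
  x <- seq(0.1, 15, length.out = 40)
  j0 <- avgflow:::besselJ01_complex(as.complex(x), 0)
  j1 <- avgflow:::besselJ01_complex(as.complex(x), 1)
  expect_lt(max(abs(Re(j0) - besselJ(x, 0))), 1e-10)
  expect_lt(max(abs(Re(j1) - besselJ(x, 1))), 1e-10)
  expect_lt(max(abs(Im(j0))), 1e-12)
})

test_that("Womersley field: Poiseuille wall shear, flow integral, alpha -> 0 limit", {
  R <- 0.003; mu <- 0.0035; rho <- 1056; T_ <- 0.8
  om <- 2 * pi / T_
  # steady only: wall shear is the Poiseuille closed form, exactly
  Q0 <- 1.2e-5
  wf <- womersley_field(R, Q0, mu = mu, rho = rho, omega = om)
  expect_rel_equal(wf$wss(0.3), 4 * mu * Q0 / (pi * R^3), 1e-12)

  # pulsatile: cross-section integral of v equals Q(t) (dense quadrature)
  wf2 <- womersley_field(R, Q0, Qn = c(0.5e-5 + 0.2e-5i, 0.1e-5i),
                         mu = mu, rho = rho, omega = om)
  r <- seq(0, R, length.out = 4000)
  for (t in c(0, 0.17, 0.43, 0.71)) {
    q_num <- sum(diff(r) * (wf2$velocity(r[-1], t) * 2 * pi * r[-1] +
                              wf2$velocity(r[-length(r)], t) * 2 * pi *
                                r[-length(r)]) / 2)
    expect_rel_equal(q_num, wf2$flow(t), 1e-5)
  }

  # alpha -> 0: oscillatory profile approaches the quasi-steady Poiseuille
  # shape (evaluate at the phase where the harmonic flow is maximal)
  wf3 <- womersley_field(R, 0, Qn = 1e-5 + 0i, mu = 1, rho = rho,
                         omega = 2 * pi / 100)   # alpha ~ 0.02
  expect_lt(wf3$alpha[1], 0.1)
  rr <- seq(0, 0.99 * R, length.out = 50)
  quasi <- 2 * 1e-5 / (pi * R^2) * (1 - (rr / R)^2)
  expect_lt(max(abs(wf3$velocity(rr, 0) - quasi)), 0.01 * max(quasi))
})

test_that("synthetic WSS patterns deliver their closed-form descriptors", {
  cyl <- coarse_cylinder()
  T_ <- 0.8
  s_rev <- synthetic_wss_pattern(cyl$wall, "reversing", tau0 = 1.3,
                                 period = T_, n_samples = 16L)
  expect_equal(osi(s_rev), rep(0.5, nrow(cyl$wall$nodes)), tolerance = 1e-12)
  expect_equal(tawss(s_rev), rep(1.3, nrow(cyl$wall$nodes)), tolerance = 1e-12)

  s_rot <- synthetic_wss_pattern(cyl$wall, "rotating", tau0 = 0.9,
                                 period = T_, n_samples = 16L)
  expect_equal(tawss(s_rot), rep(0.9, nrow(cyl$wall$nodes)), tolerance = 1e-12)

  s_uni <- synthetic_wss_pattern(cyl$wall, "unidirectional_pulsatile",
                                 tau0 = 1, tau1 = 0.4, period = T_,
                                 n_samples = 32L)
  expect_lt(max(osi(s_uni)), 1e-12)
  expect_lt(max(transwss(s_uni)$value), 1e-10)

  expect_error(synthetic_wss_pattern(cyl$wall, "nope"), "unknown pattern")
})

test_that("divergence-switching pattern: TSVI equals the hand RMS (1/r)", {
  ann <- make_annulus_surface(0.001, 0.003, n_rad = 32L, n_circ = 128L)
  s <- synthetic_wss_pattern(ann, "divergence_switching", tau0 = 1,
                             period = 0.8, n_samples = 8L)
  dv <- divergence_series(s)
  ts <- tsvi(dv, s$times, s$period)
  # the series is exactly +/- D per cell: TSVI must equal |D| to roundoff
  expect_equal(ts, abs(dv[, 1]), tolerance = 1e-12)
  # and D approximates the analytic 1/r within mesh tolerance
  rc <- sqrt(ann$tri_centroids[, 1]^2 + ann$tri_centroids[, 2]^2)
  expect_lt(max(abs(ts - 1 / rc) * rc), 0.03)
  # cycle-mean divergence vanishes
  expect_lt(max(abs(cycle_mean(s$times, t(dv), s$period))), 1e-12)
})

test_that("Carreau-Yasuda viscosity: limits and a hand-computed mid-range value", {
  p <- rheology_params()
  expect_equal(carreau_yasuda_viscosity(0, p), p$mu0)
  expect_rel_equal(carreau_yasuda_viscosity(1e7, p), p$mu_inf, 0.001)
  g <- 10
  hand <- p$mu_inf + (p$mu0 - p$mu_inf) *
    (1 + (p$lambda * g)^p$a)^((p$n - 1) / p$a)
  expect_equal(carreau_yasuda_viscosity(g, p), hand)
  expect_true(all(diff(carreau_yasuda_viscosity(10^seq(-2, 5, 0.5), p)) < 0))
  expect_error(rheology_params(mu0 = 0.001, mu_inf = 0.003), "mu0 >= mu_inf")
  expect_error(carreau_yasuda_viscosity(-1, p), "non-negative")
})

test_that("toy AVG network has the expected structure and conserves mass", {
  net <- toy_avg_network()
  expect_equal(nrow(net$segments), 6L)
  types <- vapply(net$terminations, function(x) x$type, "")
  expect_equal(sum(types == "inflow"), 1L)
  expect_equal(sum(types == "wk3"), 3L)
  expect_equal(sum(types == "pressure"), 1L)
  expect_equal(unname(net$terminations$vout$value), mmHg_to_Pa(8))
  # inertances follow the (4/3) rho l / A law
  expect_equal(net$segments$L,
               segment_inertance(net$segments$l, net$segments$A, 1056))
  sol <- simulate_network(net, toy_inflow_waveform(), dt = 4e-3, n_cycles = 3)
  expect_lt(mass_conservation_error(net, sol), 1e-10)
})

test_that("toy inflow waveform is positive, periodic and has the stated mean", {
  w <- toy_inflow_waveform()
  expect_true(all(w$values > 0))
  expect_rel_equal(waveform_mean(w), 1.5e-5, 1e-9)
  expect_identical(toy_inflow_waveform()$values, w$values)
})
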