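make_series <- function(mesh, times, period, f) {
  # f(t) -> n x 3 velocity
  arr <- array(0, c(nrow(mesh$nodes), 3, length(times)))
  for (k in seq_along(times)) arr[, , k] <- f(times[k])
  volume_series(mesh, times, arr, period)
}

test_that("cycle averaging: constants, sinusoids, alternating symmetry", {
  cyl <- coarse_cylinder()$volume
  T_ <- 0.8
  v0 <- helical_field(10, 0.3)(cyl$nodes)
  tt <- T_ * (0:15) / 16
  s_const <- make_series(cyl, tt, T_, function(t) v0)
  expect_equal(cycle_average_velocity(s_const), v0, tolerance = 1e-12)

  t64 <- T_ * (0:63) / 64
  s_sin <- make_series(cyl, t64, T_,
                       function(t) v0 * (1 + 0.7 * sin(2 * pi * t / T_)))
  expect_lt(max(abs(cycle_average_velocity(s_sin) - v0)), 1e-6 * max(abs(v0)))

  s_alt <- make_series(cyl, T_ * (0:3) / 4, T_,
                       function(t) v0 * (1 - 2 * (round(4 * t / T_) %% 2)))
  expect_lt(max(abs(cycle_average_velocity(s_alt))), 1e-12)
})

test_that("fluctuations are instantaneous minus mean with zero cycle average", {
  cyl <- coarse_cylinder()$volume
  T_ <- 0.8
  v0 <- helical_field(10, 0.3)(cyl$nodes)
  t16 <- T_ * (0:15) / 16
  steady <- make_series(cyl, t16, T_, function(t) v0)
  expect_equal(max(abs(velocity_fluctuations(steady))), 0)

  s <- make_series(cyl, t16, T_,
                   function(t) v0 + 0.2 * sin(2 * pi * t / T_))
  fl <- velocity_fluctuations(s)
  for (k in seq_along(t16)) {
    expect_equal(fl[, , k], matrix(0.2 * sin(2 * pi * t16[k] / T_),
                                   nrow(cyl$nodes), 3), tolerance = 1e-9)
  }
  flm <- cycle_mean(s$times, aperm(fl, c(3, 1, 2)), T_)
  expect_lt(max(abs(flm)), 1e-10 * max(abs(s$velocity)))
})

test_that("TKE formula: hand value, isotropy, quadratic scaling, positivity", {
  fl <- matrix(c(0.1, 0, 0), 1)
  expect_equal(tke_field(fl, rho = 1056), 5.28)
  expect_equal(tke_field(fl[, c(3, 1, 2), drop = FALSE], rho = 1056), 5.28)
  expect_equal(tke_field(3 * fl, rho = 1056), 9 * 5.28)
  expect_equal(tke_field(matrix(0, 5, 3)), rep(0, 5))
  rnd <- matrix(rnorm(30), 10)
  expect_true(all(tke_field(rnd) >= 0))
})

test_that("vorticity reconstruction is exact on affine fields", {
  cyl <- refined_cylinder()$volume
  u <- matrix(rep(c(0.3, -0.1, 0.2), each = nrow(cyl$nodes)), ncol = 3)
  expect_lt(max(abs(vorticity_field(cyl, u)$node)), 1e-10)

  Om <- 40
  vr <- helical_field(Om, 0)(cyl$nodes)
  w <- vorticity_field(cyl, vr)$node
  expect_lt(max(abs(sweep(w, 2, c(0, 0, 2 * Om)))), 1e-9 * 2 * Om)

  g <- 15
  shear <- cbind(g * cyl$nodes[, 2], 0, 0)
  ws <- vorticity_field(cyl, shear)$node
  expect_lt(max(abs(sweep(ws, 2, c(0, 0, -g)))), 1e-9 * g)
})

test_that("helicity descriptors: closed form, symmetry, irrotational zero", {
  cyl <- coarse_cylinder()$volume
  T_ <- 0.8
  t8 <- T_ * (0:7) / 8
  Om <- 50; W <- 0.2
  s <- make_series(cyl, t8, T_, function(t) helical_field(Om, W)(cyl$nodes))
  h <- helicity_descriptors(s)
  expect_rel_equal(h$h1, 2 * Om * W, 1e-9)
  expect_rel_equal(h$h2, 2 * Om * W, 1e-9)
  expect_equal(h$h4, 1)

  # two mirror-image halves: equal and opposite rotation
  n <- nrow(cyl$nodes)
  nodes2 <- rbind(cyl$nodes, sweep(cyl$nodes, 2, c(0, 0, 0.05), `+`))
  cells2 <- rbind(cyl$cells, cyl$cells + n)
  mesh2 <- volume_mesh(nodes2, cells2)
  f2 <- function(t) rbind(helical_field(Om, W)(cyl$nodes),
                          helical_field(-Om, W)(cyl$nodes))
  s2 <- make_series(mesh2, t8, T_, f2)
  h2 <- helicity_descriptors(s2)
  expect_lt(abs(h2$h1), 1e-9 * 2 * Om * W)
  expect_equal(h2$h4, 0, tolerance = 1e-9)
  expect_gt(h2$h2, 0)

  # irrotational (uniform) flow: everything vanishes, h3/h4 by convention
  s3 <- make_series(cyl, t8, T_,
                    function(t) matrix(rep(c(0.1, 0.2, 0.3), each = n), ncol = 3))
  h3 <- helicity_descriptors(s3)
  expect_equal(c(h3$h1, h3$h2, h3$h3, h3$h4), c(0, 0, 0, 0), tolerance = 1e-12)
})

test_that("h1 flips sign and h2, h4 are unchanged under mirror reflection", {
  cyl <- coarse_cylinder()$volume
  T_ <- 0.8
  t8 <- T_ * (0:7) / 8
  base <- function(p) cbind(-30 * p[, 2], 30 * p[, 1], 0.2 + 5 * p[, 1])
  mirror <- function(p) {
    q <- cbind(-p[, 1], p[, 2], p[, 3])     # reflect through x = 0
    v <- base(q)
    cbind(-v[, 1], v[, 2], v[, 3])
  }
  s_a <- make_series(cyl, t8, T_, function(t) base(cyl$nodes))
  s_b <- make_series(cyl, t8, T_, function(t) mirror(cyl$nodes))
  ha <- helicity_descriptors(s_a)
  hb <- helicity_descriptors(s_b)
  expect_equal(hb$h1, -ha$h1, tolerance = 1e-9)
  expect_equal(hb$h2, ha$h2, tolerance = 1e-9)
  expect_equal(hb$h4, ha$h4, tolerance = 1e-9)
})

test_that("h2 >= |h1| and bounds hold on random smooth fields", {
  cyl <- coarse_cylinder()$volume
  T_ <- 1
  t6 <- T_ * (0:5) / 6
  set.seed(7)
  for (rep_i in 1:5) {
    A <- matrix(rnorm(9, sd = 20), 3)
    b <- rnorm(3, sd = 0.2)
    f <- function(t) {
      sc <- 1 + 0.5 * sin(2 * pi * t / T_)
      sc * (cyl$nodes %*% A + matrix(rep(b, each = nrow(cyl$nodes)), ncol = 3))
    }
    s <- make_series(cyl, t6, T_, f)
    h <- helicity_descriptors(s)
    expect_gte(h$h2, abs(h$h1) - 1e-12 * h$h2)
    expect_true(h$h3 >= -1 && h$h3 <= 1)
    expect_true(h$h4 >= 0 && h$h4 <= 1)
    vt <- vorticity_series(s)
    l <- lnh_field(s$velocity[, , 3], vt[, , 3])
    expect_true(all(abs(l) <= 1))
  }
})

test_that("volume quadrature matches a Monte-Carlo integral within 1%", {
  cyl <- refined_cylinder()$volume
  T_ <- 1
  t6 <- T_ * (0:5) / 6
  Om <- 30; W <- 0.1; A <- 40           # v = (-Om y, Om x, W + A x)
  f <- function(t) cbind(-Om * cyl$nodes[, 2], Om * cyl$nodes[, 1],
                         W + A * cyl$nodes[, 1])
  s <- make_series(cyl, t6, T_, f)
  h <- helicity_descriptors(s)
  # helicity density (affine, exact): 2 Om W + Om A x
  set.seed(11)
  R <- 0.003; L <- 0.02
  xy <- matrix(runif(6e5, -R, R), ncol = 2)
  xy <- xy[rowSums(xy^2) < R^2, , drop = FALSE]
  dens <- 2 * Om * W + Om * A * xy[, 1]
  expect_rel_equal(h$h1, mean(dens), 0.01)
  expect_rel_equal(h$h2, mean(abs(dens)), 0.01)
})

test_that("LNH: alignment limits and the helical closed form", {
  v <- rbind(c(1, 0, 0), c(0, 1, 0), c(2, 2, 2))
  w <- rbind(c(2, 0, 0), c(1, 0, 0), c(-1, -1, -1))
  l <- lnh_field(v, w)
  expect_equal(l, c(1, 0, -1))
  expect_equal(lnh_field(matrix(0, 2, 3), matrix(1, 2, 3)), c(0, 0))

  cyl <- coarse_cylinder()$volume
  Om <- 50; W <- 0.2
  vv <- helical_field(Om, W)(cyl$nodes)
  ww <- vorticity_field(cyl, vv)$node
  r <- sqrt(cyl$nodes[, 1]^2 + cyl$nodes[, 2]^2)
  expect_lt(max(abs(lnh_field(vv, ww) - W / sqrt(Om^2 * r^2 + W^2))), 0.01)
})
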