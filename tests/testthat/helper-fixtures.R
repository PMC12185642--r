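# Shared small fixtures, built in code at test time.

# coarse cylinder reused across tests (fast)
coarse_cylinder <- function() {
  make_cylinder_mesh(R = 0.003, length = 0.02, n_circ = 12L, n_rad = 3L,
                     n_axial = 6L)
}

# refined cylinder for quantitative geometry/descriptor checks
refined_cylinder <- function() {
  make_cylinder_mesh(R = 0.003, length = 0.02, n_circ = 32L, n_rad = 8L,
                     n_axial = 12L)
}

# flat unit-square surface patch (two triangles) with +z normals
flat_patch <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  surface_mesh(nodes, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
               normals = matrix(rep(c(0, 0, 1), each = 4), ncol = 3))
}

# single regular tetrahedron volume mesh
one_tet <- function() {
  volume_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
              matrix(c(1L, 2L, 3L, 4L), 1))
}

# wss_series with a prescribed per-sample generator f(t) -> n x 3 (tangential)
patch_series <- function(surface, times, period, f) {
  arr <- array(0, c(nrow(surface$nodes), 3, length(times)))
  for (k in seq_along(times)) arr[, , k] <- f(times[k])
  wss_series(surface, times, arr, period)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * max(abs(expected), 1e-300))
}
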