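# independent brute-force oracle: scan the area-weighted CDF at the distinct
# values and interpolate the crossing
oracle_threshold <- function(values, areas, pct) {
  vs <- sort(unique(values))
  cdf <- vapply(vs, function(v) sum(areas[values <= v]), 0) / sum(areas)
  target <- pct / 100
  k <- which(cdf >= target - 1e-12)[1]
  if (k == 1L) return(vs[1])
  frac <- (target - cdf[k - 1L]) / (cdf[k] - cdf[k - 1L])
  vs[k - 1L] + frac * (vs[k] - vs[k - 1L])
}

test_that("area-weighted percentile matches the brute-force CDF oracle", {
  # uniform field: every percentile returns that value
  expect_equal(percentile_threshold(rep(7, 10), rep(1, 10), 33), 7)
  expect_equal(percentile_threshold(rep(7, 10), rep(1, 10), 66), 7)

  # 100 equal-area elements valued 1..100
  v <- 1:100
  expect_equal(percentile_threshold(v, rep(1, 100), 66),
               oracle_threshold(v, rep(1, 100), 66))

  # two elements with dominant area: the big element carries the CDF
  expect_equal(percentile_threshold(c(1, 10), c(9, 1), 50), 1)

  # randomized cross-validation against the oracle
  set.seed(3)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    vals <- round(rnorm(n), 2)
    ar <- runif(n, 0.1, 2)
    pct <- runif(1, 1, 99)
    expect_equal(percentile_threshold(vals, ar, pct),
                 oracle_threshold(vals, ar, pct), tolerance = 1e-9)
  }
  expect_error(percentile_threshold(numeric(0), NULL, 50), "empty")
  expect_error(percentile_threshold(c(1, NA), NULL, 50), "finite")
})

test_that("critical mask uses strict inequality and partitions cleanly", {
  m_low <- critical_mask(c(5, 6, 7), 4, "low")
  expect_equal(m_low$mask, c(FALSE, FALSE, FALSE))
  m_hi <- critical_mask(c(1, 2, 3), 2, "high")
  expect_equal(m_hi$mask, c(FALSE, FALSE, TRUE))
  # low-mask, high-mask and the equality set partition the elements
  v <- c(1, 2, 2, 3, 4)
  lo <- critical_mask(v, 2, "low")$mask
  hi <- critical_mask(v, 2, "high")$mask
  eq <- v == 2
  expect_true(all(lo + hi + eq == 1))
})

test_that("ROI area fractions are exact ratios", {
  areas <- c(1, 1, 2, 2)
  mask <- c(TRUE, TRUE, TRUE, TRUE)
  expect_equal(roi_area_fraction(mask, NULL, areas), 100)
  expect_equal(roi_area_fraction(!mask, NULL, areas), 0)
  expect_equal(roi_area_fraction(c(TRUE, FALSE, FALSE, FALSE), c(1L, 2L), areas), 50)
  expect_error(roi_area_fraction(mask, integer(0), areas), "empty")
})

test_that("Dice similarity: identity, disjoint, nested, symmetry, bounds", {
  areas <- rep(1, 8)
  a <- c(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(similarity_index(a, a, areas), 100)
  b <- !a
  expect_equal(similarity_index(a, b, areas), 0)
  # A subset of B with area(A) = area(B)/2 -> 2*(1/2)/(3/2)*100 = 66.67
  bb <- rep(TRUE, 8)
  aa <- c(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(similarity_index(aa, bb, areas), 200 / 3, tolerance = 1e-9)
  expect_equal(similarity_index(bb, aa, areas), similarity_index(aa, bb, areas))
  expect_equal(similarity_index(rep(FALSE, 8), rep(FALSE, 8), areas), 100)
  set.seed(5)
  for (i in 1:20) {
    x <- runif(8) > 0.5; y <- runif(8) > 0.5
    s <- similarity_index(x, y, areas)
    expect_true(s >= 0 && s <= 100)
    expect_equal(similarity_index(y, x, areas), s)
  }
})

test_that("report composition equals the individual operations bit for bit", {
  set.seed(9)
  n <- 200
  areas <- runif(n, 0.5, 1.5)
  fields <- list(tawss = runif(n, 0, 5), osi = runif(n, 0, 0.5),
                 transwss = runif(n, 0, 2), tsvi = runif(n, 0, 100))
  rois <- list(half = 1:100, rest = 101:200)
  rep_ <- criticality_report(fields, areas, rois = rois)
  rules <- default_threshold_rules()
  for (i in seq_len(nrow(rules))) {
    d <- rules$descriptor[i]
    thr <- percentile_threshold(fields[[d]], areas, rules$pct[i])
    mk <- critical_mask(fields[[d]], thr, rules$direction[i])
    rows <- rep_$table[rep_$table$descriptor == d, ]
    expect_identical(unique(rows$threshold), thr)
    expect_identical(rows$pct_area[rows$roi == "whole"],
                     roi_area_fraction(mk, NULL, areas))
    expect_identical(rows$pct_area[rows$roi == "half"],
                     roi_area_fraction(mk, rois$half, areas))
  }
})

test_that("uniform field yields 0% critical everywhere (strict inequality)", {
  n <- 50
  fields <- list(tawss = rep(1, n), osi = rep(0.2, n), transwss = rep(1, n),
                 tsvi = rep(3, n))
  rep_ <- criticality_report(fields, rep(1, n))
  expect_true(all(rep_$table$pct_area == 0))
})

test_that("high-rule fractions never increase as the percentile is raised", {
  set.seed(13)
  vals <- runif(300)
  areas <- runif(300, 0.5, 2)
  fr <- vapply(c(30, 50, 66, 80, 95), function(p) {
    thr <- percentile_threshold(vals, areas, p)
    roi_area_fraction(critical_mask(vals, thr, "high"), NULL, areas)
  }, 0)
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("fractions are invariant to element reordering and area rescaling", {
  set.seed(21)
  vals <- rnorm(100); areas <- runif(100, 0.1, 1)
  thr <- percentile_threshold(vals, areas, 66)
  f0 <- roi_area_fraction(critical_mask(vals, thr, "high"), NULL, areas)
  o <- sample(100)
  thr2 <- percentile_threshold(vals[o], areas[o], 66)
  expect_equal(thr2, thr, tolerance = 1e-12)
  f1 <- roi_area_fraction(critical_mask(vals[o], thr2, "high"), NULL, areas[o])
  expect_equal(f1, f0, tolerance = 1e-12)
  thr3 <- percentile_threshold(vals, 7.5 * areas, 66)
  f2 <- roi_area_fraction(critical_mask(vals, thr3, "high"), NULL, 7.5 * areas)
  expect_equal(f2, f0, tolerance = 1e-12)
})

test_that("whole-domain fraction of a pct rule is ~ (100 - pct)% for distinct values", {
  set.seed(31)
  vals <- runif(500)
  areas <- rep(1, 500)
  thr <- percentile_threshold(vals, areas, 66)
  fr <- roi_area_fraction(critical_mask(vals, thr, "high"), NULL, areas)
  expect_lt(abs(fr - 34), 0.5)
})

test_that("a constructed band covering 30% of an ROI reports 30%", {
  cyl <- make_cylinder_mesh(R = 0.003, length = 0.02, n_circ = 12L,
                            n_rad = 3L, n_axial = 10L)
  wall <- axial_rois(cyl$wall, list(lower = c(0, 0.01), upper = c(0.01, 0.02)))
  z <- wall$tri_centroids[, 3]
  # transWSS surrogate: high (1) inside the band z < 0.003, i.e. 30% of the
  # axial extent of the lower ROI
  vals <- as.numeric(z < 0.003)
  fields <- list(tawss = rep(1, length(z)), osi = rep(0, length(z)),
                 transwss = vals, tsvi = rep(0, length(z)))
  rep_ <- criticality_report(fields, wall$tri_areas, rois = wall$rois)
  row <- rep_$table[rep_$table$descriptor == "transwss" &
                      rep_$table$roi == "lower", ]
  # exact against the hand-computed area ratio of the constructed band
  lower <- wall$rois$lower
  expected <- 100 * sum(wall$tri_areas[lower][vals[lower] > 0]) /
    sum(wall$tri_areas[lower])
  expect_equal(row$pct_area, expected, tolerance = 1e-12)
  # and the band was built to cover 30% up to mesh discretisation
  expect_lt(abs(row$pct_area - 30), 2)
})
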