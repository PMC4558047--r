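test_that("the interpolant passes through the samples and averages at the centroid", {
  s <- data.frame(row = c(0, 0, 3), col = c(0, 3, 0),
                  v = c(0, 0, 3))
  f <- delaunay_interpolate(s, dim = c(5, 5), value_cols = "v")$v
  expect_equal(f$values[1, 1], 0)
  expect_equal(f$values[1, 4], 0)
  expect_equal(f$values[4, 1], 3)
  expect_equal(f$values[2, 2], 1)  # centroid (1, 1): barycentric mean
  expect_false(f$valid[5, 5])     # outside the hull
})

test_that("affine fields are reconstructed exactly inside the hull", {
  set.seed(21)
  n <- 40
  s <- data.frame(row = stats::runif(n, 0, 30), col = stats::runif(n, 0, 30))
  s$v <- 0.2 + 0.01 * s$row - 0.003 * s$col
  f <- delaunay_interpolate(s, dim = c(31, 31), value_cols = "v")$v
  rr <- matrix(0:30, 31, 31); cc <- t(rr)
  truth <- 0.2 + 0.01 * rr - 0.003 * cc
  expect_lt(max(abs(f$values[f$valid] - truth[f$valid])), 1e-9)
  expect_gt(sum(f$valid), 500)
  # convexity: interpolated values bounded by the sample range
  expect_gte(min(f$values[f$valid]), min(s$v) - 1e-12)
  expect_lte(max(f$values[f$valid]), max(s$v) + 1e-12)
})

test_that("interpolation agrees with an independent barycentric oracle", {
  set.seed(33)
  n <- 50
  s <- data.frame(row = stats::runif(n, 0, 40), col = stats::runif(n, 0, 40))
  s$v <- sin(s$row / 7) + cos(s$col / 9)
  f <- delaunay_interpolate(s, dim = c(41, 41), value_cols = "v")$v
  qx <- rep(0:40, each = 41); qy <- rep(0:40, 41)  # (col, row) grid order
  oracle <- bf_delaunay_interp(s$col, s$row, s$v, qx, qy)
  om <- matrix(NA_real_, 41, 41); om[cbind(qy + 1, qx + 1)] <- oracle
  both <- f$valid & !is.na(om)
  expect_gt(sum(both), 1000)
  # near-co-circular point quadruples let the two Delaunay codes pick
  # different (equally valid) diagonals; values then differ only slightly
  expect_lt(max(abs(f$values[both] - om[both])), 1e-5)
})

test_that("degenerate sample sets are rejected", {
  s <- data.frame(row = c(0, 1), col = c(0, 1), v = c(1, 2))
  expect_error(delaunay_interpolate(s, c(5, 5), "v"), "at least 3")
  s3 <- data.frame(row = 0:4, col = 0:4, v = 1:5)
  expect_error(delaunay_interpolate(s3, c(5, 5), "v"), "collinear")
  sdup <- data.frame(row = c(0, 0, 3, 3), col = c(0, 3, 0, 0), v = 1:4)
  expect_error(delaunay_interpolate(sdup, c(5, 5), "v"), "duplicate")
})

test_that("ring averaging is exact for constants and kills pure angular modes", {
  d <- c(41, 41); center <- c(20, 20)
  const <- scalar_field(matrix(2.5, d[1], d[2]))
  out <- radial_ring_average(const, center)
  expect_equal(out$values, const$values, tolerance = 1e-12)
  rr <- matrix(0:40, d[1], d[2]); cc <- t(rr)
  theta <- atan2(rr - center[1], cc - center[2])
  r <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  wave <- scalar_field((1 + r / 40) * sin(4 * theta))
  outw <- radial_ring_average(wave, center)
  expect_lt(max(abs(outw$values)), 0.2)  # discretization residual only
  expect_lt(mean(abs(outw$values)), 0.05)
})

test_that("ring averaging equals the brute-force 3-annulus means on a toy grid", {
  d <- c(41, 41); center <- c(20, 20)
  field <- scalar_field(matrix(0:40, d[1], d[2]))  # value = row index
  out <- radial_ring_average(field, center, ring_width = 5)
  bf <- bf_ring_average(field$values, field$valid, center, w = 5)
  expect_equal(out$values, bf$values, tolerance = 1e-12)
  prof <- attr(out, "profile")
  expect_equal(prof$value, bf$annulus_value, tolerance = 1e-12)
  # innermost annulus: itself plus outer neighbor only
  expect_equal(prof$value[1], mean(field$values[bf$k <= 1]))
})

test_that("annulus binning (window 1) is idempotent and empty annuli inherit", {
  d <- c(41, 41); center <- c(20, 20)
  set.seed(4)
  field <- scalar_field(matrix(stats::runif(41 * 41), 41, 41))
  once <- radial_ring_average(field, center, window = 1)
  twice <- radial_ring_average(once, center, window = 1)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
  # carve out a ring of invalid pixels spanning annuli 2-4 entirely
  rr <- matrix(0:40, 41, 41); cc <- t(rr)
  r <- sqrt((rr - 20)^2 + (cc - 20)^2)
  holey <- scalar_field(field$values, valid = !(r >= 5 & r < 25))
  out <- radial_ring_average(holey, center, ring_width = 5, window = 1)
  prof <- attr(out, "profile")
  expect_true(any(prof$flagged))
  expect_true(all(is.finite(prof$value)))  # inherited from nearest valid annulus
})

test_that("temporal interpolation blends linearly and is exact at the knots", {
  f0 <- matrix(0, 4, 4); f30 <- matrix(3, 4, 4)
  series <- field_series(c(0, 30), list(f0, f30))
  out <- temporal_interpolate(series, out_interval_s = 10)
  expect_equal(out$times, c(0, 10, 20, 30))
  expect_identical(out$fields[[1]], f0)   # bit-identical originals at knots
  expect_identical(out$fields[[4]], f30)
  expect_equal(out$fields[[2]], matrix(1, 4, 4))
  expect_equal(out$fields[[3]], matrix(2, 4, 4))
  expect_lte(max(out$times), max(series$times))  # no extrapolation
  expect_error(temporal_interpolate(field_series(0, list(f0))), "at least 2")
})

test_that("temporal interpolation recurses into per-channel field lists", {
  mk <- function(v) list(r_pn = scalar_field(matrix(v, 3, 3)),
                         g_pn = scalar_field(matrix(v / 2, 3, 3)))
  series <- field_series(c(0, 30), list(mk(0), mk(3)))
  out <- temporal_interpolate(series, 10)
  expect_equal(out$fields[[2]]$r_pn$values, matrix(1, 3, 3))
  expect_equal(out$fields[[2]]$g_pn$values, matrix(0.5, 3, 3))
})

test_that("color fields convert to pH fields with clamp propagation", {
  model <- forward_color_model()
  curve <- model_curve(model)
  nc <- model$normalized(7.0)
  d <- c(6, 6)
  fields <- list(r_pn = scalar_field(matrix(nc[1], d[1], d[2]), channel = "r_pn"),
                 g_pn = scalar_field(matrix(nc[2], d[1], d[2]), channel = "g_pn"),
                 b_pn = scalar_field(matrix(nc[3], d[1], d[2]), channel = "b_pn"))
  ph <- field_to_ph(fields, curve)
  expect_equal(ph$values, matrix(7, d[1], d[2]), tolerance = 1e-6)
  expect_equal(attr(ph, "clamped_fraction"), 0)
  # out-of-gamut pixel: beyond the basic rail
  fields$r_pn$values[2, 2] <- nc[1] + 0.2
  ph2 <- field_to_ph(fields, curve)
  expect_equal(ph2$values[2, 2], 8)
  expect_true(attr(ph2, "clamped")[2, 2])
  expect_gt(attr(ph2, "clamped_fraction"), 0)
})

test_that("recomposition renormalizes pixels back onto the unit sphere", {
  set.seed(8)
  d <- c(10, 10)
  raw <- matrix(stats::runif(300, 50, 250), ncol = 3)
  nc <- pythagorean_normalize(raw) * 1.03  # slightly off-sphere
  fields <- list(r_pn = scalar_field(matrix(nc[, 1], d[1], d[2])),
                 g_pn = scalar_field(matrix(nc[, 2], d[1], d[2])),
                 b_pn = scalar_field(matrix(nc[, 3], d[1], d[2])))
  out <- renormalize_fields(fields)
  nrm <- sqrt(out$r_pn$values^2 + out$g_pn$values^2 + out$b_pn$values^2)
  expect_lt(max(abs(nrm - 1)), 1e-12)
  expect_equal(attr(out, "qc")$median_norm_deviation, 0.03, tolerance = 1e-9)
})
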