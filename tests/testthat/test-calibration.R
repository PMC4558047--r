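test_that("calibration interpolates its knots and round-trips colors to pH", {
  curve <- model_curve()
  pts <- curve$points
  expect_equal(predict(curve, pts$ph, channel = "r"), pts$r_pn, tolerance = 1e-9)
  rt <- color_to_ph(curve, as.matrix(pts[c("r_pn", "g_pn", "b_pn")]))
  expect_equal(as.numeric(rt), pts$ph, tolerance = 1e-6)
  expect_false(any(attr(rt, "clamped")))
})

test_that("a strictly decreasing sigmoid channel is reproduced at the knots", {
  ph <- seq(5, 8, by = 0.5)
  r <- 0.9 - 0.5 / (1 + 10^(0.8 * (6.5 - ph)))  # decreasing with pH
  pts <- calibration_points(ph, r_pn = r, g_pn = 0.4, b_pn = sqrt(1 - 0.16 - r^2))
  curve <- build_calibration(pts, inversion_channel = "r")
  expect_equal(predict(curve, ph, channel = "r"), r, tolerance = 1e-6)
  expect_false(curve$increasing)
})

test_that("degenerate calibrations are rejected with informative errors", {
  ph <- seq(5, 8, by = 0.5)
  pts <- calibration_points(ph, r_pn = 0.5, g_pn = 0.4, b_pn = seq(0.9, 0.3, length.out = 7))
  expect_error(build_calibration(pts, inversion_channel = "r"),
               "not strictly monotone")
  expect_error(build_calibration(pts[1:3, ], inversion_channel = "b"),
               "at least 4")
  expect_error(build_calibration(pts[, c("ph", "r_pn")]), "missing column")
})

test_that("fitted curve recovers the forward model between knots", {
  model <- forward_color_model()
  curve <- model_curve(model)
  probe <- seq(5.05, 7.95, length.out = 20)
  truth <- model$normalized(probe)
  for (i in 1:3) {
    ch <- c("r", "g", "b")[i]
    expect_lt(max(abs(predict(curve, probe, channel = ch) - truth[, i])), 0.02)
  }
})

test_that("noisy colors invert to pH with RMSE below 0.1", {
  set.seed(5)
  model <- forward_color_model()
  curve <- model_curve(model)
  ph <- stats::runif(100, 5.2, 7.8)
  obs <- model$normalized(ph) + matrix(stats::rnorm(300, 0, 0.005), ncol = 3)
  est <- as.numeric(color_to_ph(curve, obs))
  expect_lt(sqrt(mean((est - ph)^2)), 0.1)
})

test_that("inversion is monotone and clamps out-of-span colors with a flag", {
  model <- forward_color_model()
  curve <- model_curve(model)
  v <- model$normalized(seq(5.1, 7.9, length.out = 25))
  est <- as.numeric(color_to_ph(curve, v))
  expect_true(all(diff(est) > 0))
  beyond <- model$normalized(8)  # push r_pn past the pH-8 knot value
  beyond[1] <- beyond[1] + 0.05
  res <- color_to_ph(curve, beyond)
  expect_equal(as.numeric(res), 8)
  expect_true(attr(res, "clamped"))
  low <- model$normalized(5); low[1] <- low[1] - 0.05
  res <- color_to_ph(curve, low)
  expect_equal(as.numeric(res), 5)
  expect_true(attr(res, "clamped"))
})

test_that("resolution is first-order noise over slope", {
  # linear response: r_pn falls 0.1 per pH unit
  ph <- seq(5, 8, by = 0.5)
  pts <- calibration_points(ph, r_pn = 1 - 0.1 * (ph - 4), g_pn = 0.4,
                            b_pn = 1 - 0.2 * (ph - 4))
  curve <- build_calibration(pts, inversion_channel = "r")
  expect_equal(estimate_resolution(curve, 6.5, 0.01), 0.1, tolerance = 1e-6)
  curve_b <- build_calibration(pts, inversion_channel = "b")  # slope -0.2
  expect_equal(estimate_resolution(curve_b, 6.5, 0.01), 0.05, tolerance = 1e-6)
  expect_error(estimate_resolution(curve, 6.5, 0), "> 0")
  expect_error(estimate_resolution(curve, 4.2, 0.01), "calibrated range")
})

test_that("resolution is minimized at the sigmoid inflection", {
  ph <- seq(5, 8, by = 0.25)
  r <- 0.3 + 0.5 / (1 + 10^(0.9 * (6.5 - ph)))
  pts <- calibration_points(ph, r_pn = r, g_pn = 0.4, b_pn = 0.86 - 0.4 * r)
  curve <- build_calibration(pts, inversion_channel = "r")
  grid <- seq(5.05, 7.95, by = 0.01)
  res <- estimate_resolution(curve, grid, 0.01)
  expect_lt(abs(grid[which.min(res)] - 6.5), 0.25)
})

test_that("the forward model honors the sensitivity ordering of the optode", {
  nc <- forward_color_model()$normalized(seq(5, 8, by = 0.1))
  dR <- abs(nc[nrow(nc), 1] - nc[1, 1])
  dB <- abs(nc[nrow(nc), 3] - nc[1, 3])
  dG <- diff(range(nc[, 2]))
  expect_gt(dR, dB)           # red most sensitive
  expect_lt(dG, 0.3 * dR)     # green nearly flat
})

test_that("repeated-pH points pool into one fit with a hysteresis diagnostic", {
  model <- forward_color_model()
  ph <- rep(seq(5, 8, by = 0.5), 2)
  nc <- model$normalized(ph)
  nc[1:7, 1] <- nc[1:7, 1] + 0.004   # basic->acidic pass reads slightly high
  nc[8:14, 1] <- nc[8:14, 1] - 0.004
  pts <- calibration_points(ph, nc[, 1], nc[, 2], nc[, 3],
                            direction = rep(c("down", "up"), each = 7))
  curve <- build_calibration(pts)
  expect_equal(nrow(curve$points), 7)
  expect_equal(curve$hysteresis, 0.008, tolerance = 1e-9)
})

test_that("calibration CSV and JSON serialization round-trip", {
  curve <- model_curve()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(curve$points, csv)
  pts2 <- read_calibration_csv(csv)
  expect_equal(pts2$r_pn, curve$points$r_pn, tolerance = 1e-12)
  js <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(curve, js)
  curve2 <- read_calibration_json(js)
  probe <- seq(5.1, 7.9, length.out = 30)
  expect_equal(predict(curve2, probe), predict(curve, probe), tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(r_pn = 1:3), bad, row.names = FALSE)
  expect_error(read_calibration_csv(bad), "missing column")
})

test_that("logistic fit mode reproduces a logistic response", {
  model <- forward_color_model()
  curve <- model_curve(model, method = "logistic")
  probe <- seq(5, 8, length.out = 40)
  expect_lt(max(abs(predict(curve, probe, channel = "r") -
                      model$normalized(probe)[, 1])), 0.02)
})

test_that("green-channel drift QC flags outlier frames", {
  g <- c(rep(0.40, 10) + stats::rnorm(10, 0, 1e-4), 0.46)
  flags <- qc_green_drift(g)
  expect_true(flags[11])
  expect_false(any(flags[1:10]))
})
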