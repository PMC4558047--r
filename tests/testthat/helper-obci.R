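# Shared helpers and independent oracles for the obci test suite.

# Calibration points generated straight from the renderer's forward model
# (pH 5.0-8.0 in 0.5 increments, as in the calibration protocol).
model_calibration_points <- function(model = forward_color_model(),
                                     ph = seq(5, 8, by = 0.5)) {
  nc <- model$normalized(ph)
  calibration_points(ph, nc[, 1], nc[, 2], nc[, 3], n_regions = 10L)
}

model_curve <- function(model = forward_color_model(), ...) {
  build_calibration(model_calibration_points(model), ...)
}

# Brute-force radial ring average: per-annulus means over the 3-annulus pixel
# union, computed by explicit loops over pixels (independent of the vectorized
# implementation).
bf_ring_average <- function(values, valid, center, w = 5, window = 3) {
  d <- dim(values)
  k <- matrix(NA_integer_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    r <- sqrt((i - 1 - center[1])^2 + (j - 1 - center[2])^2)
    k[i, j] <- floor(r / w)
  }
  kmax <- max(k)
  half <- (window - 1) / 2
  out_val <- rep(NA_real_, kmax + 1)
  for (kk in 0:kmax) {
    sel <- valid & k >= max(0, kk - half) & k <= kk + half
    if (any(sel)) out_val[kk + 1] <- mean(values[sel])
  }
  out <- matrix(out_val[k + 1], d[1], d[2])
  list(values = out, annulus_value = out_val, k = k)
}

# Independent piecewise-linear interpolation oracle built on deldir (a
# different Delaunay implementation than the one the package wraps):
# barycentric interpolation within each deldir triangle.
bf_delaunay_interp <- function(x, y, z, qx, qy) {
  dd <- deldir::deldir(x, y, suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  out <- rep(NA_real_, length(qx))
  for (tri in tl) {
    x1 <- tri$x[1]; x2 <- tri$x[2]; x3 <- tri$x[3]
    y1 <- tri$y[1]; y2 <- tri$y[2]; y3 <- tri$y[3]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    l1 <- ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / det
    l2 <- ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    zv <- z[tri$ptNum]
    out[inside] <- l1[inside] * zv[1] + l2[inside] * zv[2] + l3[inside] * zv[3]
  }
  out
}

# Small rendered scene: n disks on a white background, no pH gradient.
render_uniform_scene <- function(ph = 6.5, n_sites = 20, dim = c(64, 64),
                                 noise_sd = 0, seed = 7, quantize = TRUE) {
  cfg <- render_config(dim = dim, n_sites = n_sites, noise_sd = noise_sd,
                       aggregate_fraction = 0)
  beads <- place_beads(cfg, seed = seed)
  img <- render_frame(matrix(ph, dim[1], dim[2]), beads, cfg, seed = seed,
                      quantize = quantize)
  list(cfg = cfg, beads = beads, img = img,
       truth_mask = bead_truth_mask(beads, dim, cfg$bead_radius_px))
}
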