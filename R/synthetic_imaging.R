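#' Forward optode color model (pH -> bead color)
#'
#' The package's reference forward model for rendering synthetic bead images:
#' a 4-parameter logistic per raw RGB channel between a blue bead color at low
#' pH and an orange one at high pH, with the steepest response near pH 6.5.
#' After Pythagorean normalization the red channel is the most sensitive, the
#' blue channel distinctly less so, and green is nearly flat — the sensitivity
#' ordering expected of this optode chemistry. The numbers are the package's
#' own reference truth (no tabulated optode response exists to transcribe) and
#' are deliberately kept separate from fitted calibrations so that round-trip
#' tests stay honest.
#'
#' @param low,high Raw 8-bit RGB endpoints at the acidic / basic rail.
#' @param midpoint Inflection pH (default 6.5).
#' @param slope Logistic steepness (decades of response per pH unit scale).
#' @return An object of class `obci_forward_model` with functions
#'   `raw(ph)` (n x 3 matrix, 0-255 scale) and `normalized(ph)` (n x 3
#'   unit-norm matrix).
#' @export
forward_color_model <- function(low = c(70, 90, 200), high = c(230, 95, 110),
                                midpoint = 6.5, slope = 0.7) {
  raw <- function(ph) {
    w <- 1 / (1 + 10^(slope * (midpoint - ph)))
    cbind(low[1] + (high[1] - low[1]) * w,
          low[2] + (high[2] - low[2]) * w,
          low[3] + (high[3] - low[3]) * w)
  }
  normalized <- function(ph) {
    m <- raw(ph)
    m / sqrt(rowSums(m^2))
  }
  structure(list(raw = raw, normalized = normalized,
                 params = list(low = low, high = high, midpoint = midpoint,
                               slope = slope)),
            class = "obci_forward_model")
}

#' Renderer configuration
#'
#' Defaults emulate the study conditions: a region of interest of about
#' 2 mm^2, bead sites with nearest-neighbor spacing in the 50-100 µm range
#' (including small aggregates), 30 s frame interval, and a near-white
#' substrate. True beads are 1-3 µm; at ROI scale that would be sub-pixel, so
#' beads are rendered as disks of `bead_radius_px` pixels (default 2) and
#' resolution statements are made in ring widths, not bead diameters.
#'
#' @param dim Image shape `c(rows, cols)`.
#' @param um_per_px Pixel size (µm); 128 px x 11 µm gives a 1.4 mm (~2 mm^2)
#'   ROI.
#' @param n_sites Number of bead sites to place.
#' @param bead_radius_px Rendered bead disk radius (px).
#' @param min_spacing_um Minimum spacing between non-aggregate sites (µm).
#' @param aggregate_fraction Fraction of sites that become small aggregates.
#' @param aggregate_sizes Possible aggregate sizes (beads per cluster).
#' @param frame_interval_s Acquisition interval (s).
#' @param noise_sd Additive Gaussian camera noise per channel (8-bit counts).
#' @param background Near-white substrate color (raw RGB).
#' @param model Forward color model (see [forward_color_model()]).
#' @return A list of class `obci_render_config`.
#' @export
render_config <- function(dim = c(128, 128), um_per_px = 11,
                          n_sites = 250, bead_radius_px = 2,
                          min_spacing_um = 50, aggregate_fraction = 0.15,
                          aggregate_sizes = 2:6, frame_interval_s = 30,
                          noise_sd = 2, background = c(250, 248, 245),
                          model = forward_color_model()) {
  structure(list(dim = dim, um_per_px = um_per_px, n_sites = n_sites,
                 bead_radius_px = bead_radius_px,
                 min_spacing_um = min_spacing_um,
                 aggregate_fraction = aggregate_fraction,
                 aggregate_sizes = aggregate_sizes,
                 frame_interval_s = frame_interval_s, noise_sd = noise_sd,
                 background = background, model = model),
            class = "obci_render_config")
}

#' Place bead sites (with aggregates) on the image
#'
#' Sites are drawn uniformly at random subject to a minimum spacing between
#' non-aggregate sites; a configured fraction of sites then becomes a small
#' aggregate of 2-6 touching disks (aggregates are data like single beads).
#' Placement is deterministic under a fixed seed.
#'
#' @param cfg An [render_config()].
#' @param seed Integer RNG seed.
#' @return A data.frame `bead_id, site_id, row, col, aggregate` (0-based
#'   fractional pixel coordinates).
#' @export
place_beads <- function(cfg, seed = 1) {
  set.seed(seed)
  d <- cfg$dim
  min_px <- cfg$min_spacing_um / cfg$um_per_px
  margin <- cfg$bead_radius_px + 1
  rows <- cols <- numeric(0)
  tries <- 0L
  max_tries <- 400L * cfg$n_sites
  while (length(rows) < cfg$n_sites) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("infeasible bead packing: could not place ", cfg$n_sites,
           " sites at ", cfg$min_spacing_um, " um spacing after ",
           max_tries, " tries")
    r <- stats::runif(1, margin, d[1] - 1 - margin)
    c <- stats::runif(1, margin, d[2] - 1 - margin)
    if (length(rows) == 0 ||
        min((rows - r)^2 + (cols - c)^2) >= min_px^2) {
      rows <- c(rows, r); cols <- c(cols, c)
    }
  }
  n_agg <- round(cfg$aggregate_fraction * cfg$n_sites)
  agg_sites <- if (n_agg > 0) sample(cfg$n_sites, n_agg) else integer(0)
  out <- data.frame(bead_id = seq_len(cfg$n_sites),
                    site_id = seq_len(cfg$n_sites),
                    row = rows, col = cols,
                    aggregate = seq_len(cfg$n_sites) %in% agg_sites)
  extra <- list()
  next_id <- cfg$n_sites
  for (s in agg_sites) {
    k <- sample(cfg$aggregate_sizes, 1)
    r0 <- rows[s]; c0 <- cols[s]
    for (j in seq_len(k - 1)) {
      theta <- stats::runif(1, 0, 2 * pi)
      r0 <- min(max(r0 + 2 * cfg$bead_radius_px * sin(theta), margin), d[1] - 1 - margin)
      c0 <- min(max(c0 + 2 * cfg$bead_radius_px * cos(theta), margin), d[2] - 1 - margin)
      next_id <- next_id + 1L
      extra[[length(extra) + 1L]] <-
        data.frame(bead_id = next_id, site_id = s, row = r0, col = c0,
                   aggregate = TRUE)
    }
  }
  if (length(extra) > 0) out <- rbind(out, do.call(rbind, extra))
  out
}

#' Pixel set covered by the rendered bead disks (ground-truth mask)
#'
#' @param beads Data.frame from [place_beads()].
#' @param dim Image shape.
#' @param radius_px Disk radius in pixels.
#' @return Logical `rows x cols` matrix.
#' @export
bead_truth_mask <- function(beads, dim, radius_px = 2) {
  mask <- matrix(FALSE, dim[1], dim[2])
  off <- expand.grid(dr = -ceiling(radius_px):ceiling(radius_px),
                     dc = -ceiling(radius_px):ceiling(radius_px))
  off <- off[off$dr^2 + off$dc^2 <= radius_px^2, ]
  for (i in seq_len(nrow(beads))) {
    rr <- round(beads$row[i]) + off$dr + 1
    cc <- round(beads$col[i]) + off$dc + 1
    ok <- rr >= 1 & rr <= dim[1] & cc >= 1 & cc <= dim[2]
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

#' Render one reflectance frame from a true pH field
#'
#' Background pixels take the near-white substrate color; bead-disk pixels
#' take the forward-model color at the local true pH. Gaussian camera noise is
#' added per channel, values are clipped to `[0, 255]` and (by default)
#' quantized to 8 bits last. `quantize = FALSE` keeps the float radiometry,
#' which is useful for isolating color-model errors from quantization in
#' tests.
#'
#' @param ph_field `rows x cols` true pH matrix.
#' @param beads Data.frame from [place_beads()].
#' @param cfg An [render_config()].
#' @param seed Optional RNG seed for the noise draw.
#' @param quantize Round to integer 8-bit counts (default `TRUE`).
#' @return `rows x cols x 3` array on the 0-255 scale.
#' @export
render_frame <- function(ph_field, beads, cfg, seed = NULL, quantize = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  d <- cfg$dim
  stopifnot(all(dim(ph_field) == d))
  img <- array(rep(cfg$background, each = d[1] * d[2]), dim = c(d, 3))
  mask <- bead_truth_mask(beads, d, cfg$bead_radius_px)
  cols <- cfg$model$raw(ph_field[mask])
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- cols[, ch]
    img[, , ch] <- plane
  }
  if (cfg$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, cfg$noise_sd), dim = dim(img))
  img <- pmin(pmax(img, 0), 255)
  if (quantize) img <- round(img)
  img
}

#' Render a full image stack from a simulation
#'
#' @param sim An `obci_sim`.
#' @param beads Data.frame from [place_beads()].
#' @param cfg An [render_config()].
#' @param center Source center, 0-based `(row, col)`.
#' @param times Frame times (s); defaults to the simulation output times.
#' @param seed Base RNG seed; frame `i` uses `seed + i`.
#' @param quantize See [render_frame()].
#' @return List with `images`, `truth` (list of pH matrices), `times`.
#' @export
render_stack <- function(sim, beads, cfg, center, times = sim$times,
                         seed = 1, quantize = TRUE) {
  truth <- lapply(times, function(t)
    rasterize_ph(sim, t, cfg$dim, center, cfg$um_per_px))
  images <- lapply(seq_along(times), function(i)
    render_frame(truth[[i]], beads, cfg, seed = seed + i, quantize = quantize))
  list(images = images, truth = truth, times = times)
}

preset_transport_config <- function(preset, duration_s, domain_radius_um) {
  switch(preset,
    "lateral-base" = transport_config(
      geometry = "lateral", source_ph = 8.5, bulk_ph = 4.5,
      pore_radius_um = 100, domain_radius_um = domain_radius_um,
      dr_um = 20, duration_s = duration_s, output_interval_s = 30),
    "hemispherical-base" = transport_config(
      geometry = "hemispherical", source_ph = 8.5, bulk_ph = 4.5,
      pore_radius_um = 100, domain_radius_um = domain_radius_um,
      dr_um = 20, duration_s = duration_s, output_interval_s = 30),
    "lateral-acid" = transport_config(
      geometry = "lateral", source_ph = 3.5, bulk_ph = 7.5,
      pore_radius_um = 100, domain_radius_um = domain_radius_um,
      dr_um = 20, duration_s = duration_s, output_interval_s = 30),
    stop("unknown preset: ", preset))
}

#' List the available fixture presets
#'
#' @return Character vector of preset names.
#' @export
fixture_presets <- function() {
  c("lateral-base", "hemispherical-base", "lateral-acid", "calibration-series")
}

#' Build a self-contained synthetic experiment fixture
#'
#' Simulates (or, for the calibration series, fixes) true pH fields, renders
#' the bead-image stack, and writes a self-describing directory:
#' `frames/NNNN.png`, `truth/ph_NNNN.tif` (32-bit float), `beads.csv`,
#' `calibration.csv` (pH 5.0-8.0 in 0.5 increments, as in the calibration
#' protocol), `config.yaml` and `seed.txt`. Everything is reproducible from
#' the seed.
#'
#' @param preset One of [fixture_presets()].
#' @param seed Integer seed.
#' @param dir Output directory (`NULL` keeps everything in memory).
#' @param n_frames Number of frames (ignored for the calibration series).
#' @param cfg Optional [render_config()] override.
#' @return (Invisibly) a ground-truth bundle: list with `times`, `images`,
#'   `truth`, `beads`, `bead_truth` (per-bead pH and color per frame),
#'   `model`, `calibration`, `center`, `cfg`, `sim` (when simulated).
#' @export
make_fixture <- function(preset = fixture_presets(), seed = 1, dir = NULL,
                         n_frames = 20, cfg = render_config()) {
  preset <- match.arg(preset)
  center <- (cfg$dim - 1) / 2
  cal_ph <- seq(5, 8, by = 0.5)
  cal <- calibration_points(
    ph = cal_ph,
    r_pn = cfg$model$normalized(cal_ph)[, 1],
    g_pn = cfg$model$normalized(cal_ph)[, 2],
    b_pn = cfg$model$normalized(cal_ph)[, 3],
    n_regions = 10L)
  beads <- place_beads(cfg, seed = seed)
  sim <- NULL
  if (preset == "calibration-series") {
    times <- (seq_along(cal_ph) - 1) * cfg$frame_interval_s
    truth <- lapply(cal_ph, function(p) matrix(p, cfg$dim[1], cfg$dim[2]))
    images <- lapply(seq_along(cal_ph), function(i)
      render_frame(truth[[i]], beads, cfg, seed = seed + i))
    stack <- list(images = images, truth = truth, times = times)
  } else {
    half_diag <- sqrt(sum(((cfg$dim - 1) / 2)^2)) * cfg$um_per_px
    tcfg <- preset_transport_config(preset,
                                    duration_s = (n_frames - 1) * cfg$frame_interval_s,
                                    domain_radius_um = half_diag + 200)
    sim <- simulate_propagation(tcfg)
    times <- (seq_len(n_frames) - 1) * cfg$frame_interval_s
    stack <- render_stack(sim, beads, cfg, center, times = times, seed = seed)
  }
  ph_at_beads <- function(truth_frame)
    truth_frame[cbind(round(beads$row) + 1, round(beads$col) + 1)]
  bead_truth <- do.call(rbind, lapply(seq_along(stack$times), function(i) {
    ph <- ph_at_beads(stack$truth[[i]])
    nc <- cfg$model$normalized(ph)
    data.frame(t_s = stack$times[i], bead_id = beads$bead_id, ph = ph,
               r_pn = nc[, 1], g_pn = nc[, 2], b_pn = nc[, 3])
  }))
  bundle <- list(preset = preset, seed = seed, times = stack$times,
                 images = stack$images, truth = stack$truth, beads = beads,
                 bead_truth = bead_truth, model = cfg$model,
                 calibration = cal, center = center, cfg = cfg, sim = sim)
  if (!is.null(dir)) write_fixture(bundle, dir)
  invisible(bundle)
}

write_fixture <- function(bundle, dir) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(bundle$times)) {
    write_image_png(bundle$images[[i]],
                    file.path(dir, "frames", sprintf("%04d.png", i - 1)))
    write_field_tiff(bundle$truth[[i]],
                     file.path(dir, "truth", sprintf("ph_%04d.tif", i - 1)))
  }
  utils::write.csv(bundle$beads, file.path(dir, "beads.csv"), row.names = FALSE)
  write_calibration_csv(bundle$calibration, file.path(dir, "calibration.csv"))
  cfg <- bundle$cfg
  yaml::write_yaml(list(
    preset = bundle$preset,
    dim = as.integer(cfg$dim), um_per_px = cfg$um_per_px,
    n_sites = cfg$n_sites, bead_radius_px = cfg$bead_radius_px,
    min_spacing_um = cfg$min_spacing_um,
    aggregate_fraction = cfg$aggregate_fraction,
    frame_interval_s = cfg$frame_interval_s, noise_sd = cfg$noise_sd,
    background = cfg$background,
    center = as.numeric(bundle$center),
    forward_model = cfg$model$params
  ), file.path(dir, "config.yaml"))
  writeLines(as.character(bundle$seed), file.path(dir, "seed.txt"))
  invisible(dir)
}
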