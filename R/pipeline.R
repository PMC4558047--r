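#' Run configuration for the imaging pipeline
#'
#' Collects the experiment geometry and processing settings shared by the
#' pipeline commands. A copy is echoed verbatim into every output directory so
#' results are self-describing.
#'
#' @param center Source (pore) center, 0-based `(row, col)` pixels.
#' @param pore_radius_um Pore radius (µm).
#' @param um_per_px Pixel size (µm).
#' @param frame_interval_s Acquisition interval (s, default 30).
#' @param output_interval_s Temporal-interpolation output interval (s,
#'   default 10).
#' @param ring_width_px Annulus width for radial averaging (px, default 5).
#' @param target_ph Front-tracking target (default 6.5).
#' @param inversion_channel Calibration inversion channel (default `"r"`).
#' @param threshold Manual mask threshold (`NULL` = Otsu).
#' @param score_method Bead score, see [bead_score()].
#' @param geometry `"lateral"` or `"hemispherical"` (metadata).
#' @return A list of class `obci_run_config`.
#' @export
run_config <- function(center, pore_radius_um = 100, um_per_px = 11,
                       frame_interval_s = 30, output_interval_s = 10,
                       ring_width_px = 5, target_ph = 6.5,
                       inversion_channel = "r", threshold = NULL,
                       score_method = "chroma_darkness",
                       geometry = "lateral") {
  stopifnot(length(center) == 2, um_per_px > 0, frame_interval_s > 0,
            output_interval_s > 0, ring_width_px >= 1)
  structure(list(center = center, pore_radius_um = pore_radius_um,
                 um_per_px = um_per_px, frame_interval_s = frame_interval_s,
                 output_interval_s = output_interval_s,
                 ring_width_px = ring_width_px, target_ph = target_ph,
                 inversion_channel = inversion_channel, threshold = threshold,
                 score_method = score_method, geometry = geometry),
            class = "obci_run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with [run_config()] fields.
#' @return An `obci_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Calibrate from images or a CSV of measured colors
#'
#' Builds a calibration curve either from a measured-color CSV
#' (`ph, r_pn, g_pn, b_pn, ...`) or from calibration frames at known pH:
#' each frame is thresholded, bead colors are extracted, and their mean and
#' per-channel dispersion become one calibration point. The QC report carries
#' the per-pH dispersion, the direction-hysteresis diagnostic and the knot
#' round-trip RMSE.
#'
#' @param csv Path to a calibration CSV (or a data.frame), or `NULL`.
#' @param frames List of `rows x cols x 3` arrays (0-255), or `NULL`.
#' @param ph Known pH per frame (required with `frames`).
#' @param config An [run_config()] (threshold and inversion settings).
#' @param out Optional output directory (writes `calibration.json` and
#'   `calibration_qc.csv`).
#' @return An `obci_calibration` with attribute `qc`.
#' @export
obci_calibrate <- function(csv = NULL, frames = NULL, ph = NULL,
                           config = run_config(center = c(0, 0)), out = NULL) {
  if (!is.null(csv)) {
    points <- if (is.data.frame(csv)) {
      missing_cols <- setdiff(c("ph", "r_pn", "g_pn", "b_pn"), names(csv))
      if (length(missing_cols) > 0)
        stop("calibration data missing column(s): ",
             paste(missing_cols, collapse = ", "))
      csv
    } else read_calibration_csv(csv)
  } else if (!is.null(frames)) {
    if (is.null(ph) || length(ph) != length(frames))
      stop("with frames, supply one known pH per frame")
    points <- do.call(rbind, lapply(seq_along(frames), function(i) {
      mask <- build_mask(frames[[i]], threshold = config$threshold,
                         method = config$score_method)
      s <- extract_samples(frames[[i]], mask, t = 0)
      calibration_points(ph = ph[i],
                         r_pn = mean(s$r_pn), g_pn = mean(s$g_pn),
                         b_pn = mean(s$b_pn),
                         sd_r = stats::sd(s$r_pn), sd_g = stats::sd(s$g_pn),
                         sd_b = stats::sd(s$b_pn), n_regions = nrow(s))
    }))
  } else stop("supply either csv or frames")
  curve <- build_calibration(points, inversion_channel = config$inversion_channel)
  rt <- color_to_ph(curve, as.matrix(curve$points[c("r_pn", "g_pn", "b_pn")]))
  qc <- list(knot_roundtrip_rmse = sqrt(mean((as.numeric(rt) - curve$points$ph)^2)),
             hysteresis = curve$hysteresis,
             dispersion = points[intersect(names(points),
                                           c("ph", "sd_r", "sd_g", "sd_b"))])
  attr(curve, "qc") <- qc
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_calibration_json(curve, file.path(out, "calibration.json"))
    utils::write.csv(points, file.path(out, "calibration_qc.csv"), row.names = FALSE)
  }
  curve
}

#' Reconstruct continuous pH fields from a frame stack
#'
#' The full reconstruction pipeline, one frame at a time: (1) threshold each
#' frame and build the consensus bead mask for the run, (2) extract per-pixel
#' bead colors from the unprocessed frames, (3) Delaunay-interpolate each
#' color channel, (4) radially ring-average the channels around the source,
#' re-normalize each pixel, then interpolate the channel fields to the output
#' interval in time and invert to pH through the calibration.
#'
#' @param frames List of `rows x cols x 3` arrays (0-255) or a [read_frames()]
#'   result.
#' @param curve An `obci_calibration`.
#' @param config An [run_config()].
#' @param times Frame timestamps (s); defaults to the frame interval grid.
#' @param out Optional output directory (pH TIFFs + annulus profile CSV).
#' @return An `obci_series` of pH fields with attributes `qc` (per-frame
#'   renormalization deviation, green drift flags, mask report) and
#'   `profiles`.
#' @export
obci_reconstruct <- function(frames, curve, config, times = NULL, out = NULL) {
  if (is.list(frames) && !is.null(frames$images)) {
    if (is.null(times)) times <- frames$times
    frames <- frames$images
  }
  if (is.null(times)) times <- (seq_along(frames) - 1) * config$frame_interval_s
  masks <- lapply(frames, build_mask, threshold = config$threshold,
                  method = config$score_method)
  mc <- if (length(masks) >= 2) mask_consistency(masks) else
    list(consensus = masks[[1]], jaccard = 1, flagged = integer(0))
  samples <- lapply(seq_along(frames), function(i)
    extract_samples(frames[[i]], mc$consensus, t = times[i]))
  mean_g <- vapply(samples, function(s) mean(s$g_pn), numeric(1))
  d <- dim(frames[[1]])[1:2]
  renorm_dev <- numeric(length(frames))
  channel_fields <- lapply(seq_along(frames), function(i) {
    f <- delaunay_interpolate(samples[[i]], d)
    f <- lapply(f, radial_ring_average, center = config$center,
                ring_width = config$ring_width_px)
    names(f) <- c("r_pn", "g_pn", "b_pn")
    f <- renormalize_fields(f)
    renorm_dev[i] <<- attr(f, "qc")$median_norm_deviation
    f
  })
  series <- field_series(times, channel_fields, center = config$center,
                         pore_radius_px = config$pore_radius_um / config$um_per_px,
                         um_per_px = config$um_per_px)
  series <- temporal_interpolate(series, config$output_interval_s)
  ph_fields <- lapply(series$fields, field_to_ph, curve = curve)
  ph_series <- field_series(series$times, ph_fields, center = config$center,
                            pore_radius_px = config$pore_radius_um / config$um_per_px,
                            um_per_px = config$um_per_px)
  profiles <- lapply(seq_along(ph_fields), function(i) {
    ra <- radial_ring_average(ph_fields[[i]], config$center,
                              ring_width = config$ring_width_px)
    attr(ra, "profile")
  })
  attr(ph_series, "qc") <- list(median_renorm_deviation = renorm_dev,
                                green_drift_flagged = which(qc_green_drift(mean_g)),
                                mask_jaccard = mc$jaccard,
                                mask_flagged = mc$flagged)
  attr(ph_series, "profiles") <- profiles
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    prof_path <- file.path(out, "annulus_profiles.csv")
    if (file.exists(prof_path)) file.remove(prof_path)
    for (i in seq_along(ph_fields)) {
      vals <- ph_fields[[i]]$values
      vals[!ph_fields[[i]]$valid] <- NaN
      write_field_tiff(vals, file.path(out, sprintf("ph_%04d.tif", i - 1)))
      write_profile_csv(profiles[[i]], ph_series$times[i], config$um_per_px,
                        prof_path)
    }
  }
  ph_series
}

#' Track the front of a reconstructed pH series
#'
#' @param ph_series An `obci_series` of pH fields.
#' @param config An [run_config()].
#' @param window Smoothing window (consecutive measurements, default 6).
#' @param out Optional output directory (`front_trace.csv`,
#'   `front_trace.png`).
#' @return A smoothed `obci_front_trace`.
#' @export
obci_track <- function(ph_series, config, window = 6, out = NULL) {
  trace <- trace_front(ph_series, target_ph = config$target_ph,
                       ring_width = config$ring_width_px,
                       pore_radius_um = config$pore_radius_um)
  sm <- smooth_trace(trace, window)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_trace_csv(sm, file.path(out, "front_trace.csv"))
    plot_front_trace(sm, file = file.path(out, "front_trace.png"))
  }
  sm
}

#' One-command synthetic end-to-end run
#'
#' Simulates a lateral base-propagation experiment, renders the bead-image
#' stack, calibrates from a rendered calibration series, reconstructs the pH
#' field series, tracks the front, and compares everything against the
#' simulated ground truth. Because the optode only reports within its
#' calibrated range, truth is clipped to that range before the RMSE is
#' computed.
#'
#' @param seed Integer seed controlling placement and noise.
#' @param n_frames Number of acquired frames (default 20).
#' @param preset Experiment preset (default `"lateral-base"`).
#' @param cfg Optional [render_config()].
#' @param out Optional output directory.
#' @return List: `ph_rmse`, `front` (reconstructed trace), `truth_front`,
#'   `front_max_offset_px`, `curve`, `bundle`, `ph_series`, plus the QC
#'   attributes of the reconstruction.
#' @export
obci_e2e <- function(seed = 1, n_frames = 20, preset = "lateral-base",
                     cfg = render_config(), out = NULL) {
  bundle <- make_fixture(preset, seed = seed, dir = out, n_frames = n_frames,
                         cfg = cfg)
  cal_bundle <- make_fixture("calibration-series", seed = seed + 1000, cfg = cfg)
  rc <- run_config(center = bundle$center,
                   pore_radius_um = if (!is.null(bundle$sim))
                     bundle$sim$cfg$pore_radius_um else 100,
                   um_per_px = cfg$um_per_px,
                   frame_interval_s = cfg$frame_interval_s)
  curve <- obci_calibrate(frames = cal_bundle$images,
                          ph = seq(5, 8, by = 0.5), config = rc)
  ph_series <- obci_reconstruct(bundle$images, curve, rc, times = bundle$times)
  # compare at acquired timestamps against truth clipped to the calibrated range
  rng <- curve$ph_range
  errs <- unlist(lapply(seq_along(bundle$times), function(i) {
    j <- which(abs(ph_series$times - bundle$times[i]) < 1e-9)
    if (length(j) != 1) return(NULL)
    f <- ph_series$fields[[j]]
    tr <- pmin(pmax(bundle$truth[[i]], rng[1]), rng[2])
    (f$values[f$valid] - tr[f$valid])
  }))
  ph_rmse <- sqrt(mean(errs^2))
  front <- trace_front(ph_series, target_ph = 6.5, ring_width = rc$ring_width_px)
  truth_front <- sim_front_trace(bundle$sim, target_ph = 6.5)
  common <- intersect(front$t_s, truth_front$t_s)
  off <- vapply(common, function(t) {
    a <- front$radius_um[front$t_s == t][1]
    b <- truth_front$radius_um[truth_front$t_s == t][1]
    abs(a - b) / cfg$um_per_px
  }, numeric(1))
  off <- off[is.finite(off)]
  list(ph_rmse = ph_rmse, front = front, truth_front = truth_front,
       front_max_offset_px = if (length(off)) max(off) else NA_real_,
       curve = curve, bundle = bundle, ph_series = ph_series,
       qc = attr(ph_series, "qc"))
}
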