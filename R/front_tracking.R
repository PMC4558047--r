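#' Locate the radius of a target-pH circle on a radial profile
#'
#' Scans an annulus-averaged pH profile outward from the source and returns
#' the radius at which the profile crosses the target pH (default 6.5, the
#' grayish-green front color used to track propagation), by linear
#' interpolation between the two adjacent annuli that bracket the target.
#' When over-titration behind the front produces several bracketing pairs, the
#' outermost crossing on the monotone run attached to the source is used and
#' the multiplicity is reported as a quality flag.
#'
#' @param r Radii (any units, strictly increasing).
#' @param ph pH values at those radii (`NA`s dropped).
#' @param target_ph Target pH (default 6.5).
#' @return A list: `radius` (in the units of `r`; `NA` if no crossing),
#'   `status` (`"ok"` or `"no_crossing"`), `n_crossings`, and `quality`
#'   (`1 / n_crossings`; `NA` when the front is absent).
#' @export
locate_front <- function(r, ph, target_ph = 6.5) {
  keep <- is.finite(r) & is.finite(ph)
  r <- r[keep]; ph <- ph[keep]
  if (length(r) < 2) stop("profile needs at least 2 annuli")
  if (any(diff(r) <= 0)) stop("radii must be strictly increasing")
  d <- ph - target_ph
  n <- length(d)
  # enumerate distinct crossings: exact node hits (runs of zeros count once)
  # and strict sign changes between adjacent annuli
  cross_idx <- integer(0)   # index of the annulus pair carrying the crossing
  cross_r <- numeric(0)
  z <- which(d == 0)
  if (length(z) > 0) {
    run_start <- z[c(TRUE, diff(z) > 1)]
    cross_idx <- c(cross_idx, pmax(run_start - 1L, 1L))
    cross_r <- c(cross_r, r[run_start])
  }
  sc <- which(d[-n] * d[-1] < 0)
  if (length(sc) > 0) {
    cross_idx <- c(cross_idx, sc)
    cross_r <- c(cross_r,
                 r[sc] + (r[sc + 1] - r[sc]) * (target_ph - ph[sc]) /
                   (ph[sc + 1] - ph[sc]))
  }
  if (length(cross_idx) == 0) {
    return(list(radius = NA_real_, status = "no_crossing",
                n_crossings = 0L, quality = NA_real_))
  }
  ord <- order(cross_idx)
  cross_idx <- cross_idx[ord]; cross_r <- cross_r[ord]
  # monotone run attached to the source: crossings there take precedence
  dd <- diff(ph)
  nz <- which(dd != 0)
  if (length(nz) == 0) {
    run_end <- n
  } else {
    sgn <- sign(dd[nz[1]])
    bad <- which(sign(dd) == -sgn)
    run_end <- if (length(bad) == 0) n else bad[1]
  }
  in_run <- which(cross_idx < run_end | cross_idx == 1L)
  pick <- if (length(in_run) > 0) max(in_run) else 1L
  list(radius = cross_r[pick], status = "ok",
       n_crossings = length(cross_idx), quality = 1 / length(cross_idx))
}

#' Trace the target-pH front radius over time
#'
#' Applies [locate_front()] to the annulus-averaged pH profile of each frame
#' of a pH field series, producing a distance-versus-time trace of the front
#' from the pore center (radii measured from the center; the pore radius is
#' carried as metadata, not subtracted). Frames without a crossing (front not
#' yet emerged, or beyond the ROI) are recorded as missing, not errors.
#'
#' @param series An `obci_series` of pH fields (from [field_to_ph()]), with
#'   `center` and `um_per_px` set.
#' @param target_ph Target pH (default 6.5).
#' @param ring_width Annulus width in pixels for the radial profile.
#' @param pore_radius_um Pore radius metadata (µm).
#' @return A data.frame `t_s, radius_um, quality, n_crossings, status` of
#'   class `obci_front_trace` with attributes `target_ph`, `pore_radius_um`.
#' @export
trace_front <- function(series, target_ph = 6.5, ring_width = 5,
                        pore_radius_um = NA_real_) {
  if (is.null(series$center)) stop("series has no source center")
  rows <- lapply(seq_along(series$times), function(i) {
    f <- series$fields[[i]]
    ra <- radial_ring_average(f, series$center, ring_width = ring_width)
    prof <- attr(ra, "profile")
    loc <- locate_front(prof$r_mid_px * series$um_per_px, prof$value, target_ph)
    data.frame(t_s = series$times[i],
               radius_um = loc$radius,
               quality = loc$quality,
               n_crossings = loc$n_crossings,
               status = loc$status)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("obci_front_trace", "data.frame"),
            target_ph = target_ph, pore_radius_um = pore_radius_um)
}

#' Trace a front directly on radial pH profiles
#'
#' Same as [trace_front()] but for profile matrices (e.g. simulator output or
#' truth fields), bypassing the raster stage.
#'
#' @param times Timestamps (s).
#' @param r_um Radii (µm), shared across frames.
#' @param ph_mat `length(times) x length(r_um)` matrix of pH profiles.
#' @param target_ph Target pH.
#' @param pore_radius_um Pore radius metadata (µm).
#' @return An `obci_front_trace` data.frame.
#' @export
trace_front_profiles <- function(times, r_um, ph_mat, target_ph = 6.5,
                                 pore_radius_um = NA_real_) {
  rows <- lapply(seq_along(times), function(i) {
    loc <- locate_front(r_um, ph_mat[i, ], target_ph)
    data.frame(t_s = times[i], radius_um = loc$radius, quality = loc$quality,
               n_crossings = loc$n_crossings, status = loc$status)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("obci_front_trace", "data.frame"),
            target_ph = target_ph, pore_radius_um = pore_radius_um)
}

#' Smooth a front trace with a centered moving average
#'
#' Averages `window` consecutive measurements (the reported radius-versus-time
#' traces are averages of 6 consecutive measurements); each smoothed point is
#' placed at the mean time of its window, so a linear-in-time trace is left
#' unchanged. Missing radii are excluded from their windows. Edges use the
#' frames available.
#'
#' @param trace An `obci_front_trace`.
#' @param window Number of consecutive measurements to average (default 6).
#' @return A data.frame `t_s, radius_um, quality, smoothed_radius_um` (with
#'   `t_s` at window centers).
#' @export
smooth_trace <- function(trace, window = 6) {
  if (window < 1) stop("window must be >= 1")
  n <- nrow(trace)
  lo_off <- floor((window - 1) / 2)
  hi_off <- ceiling((window - 1) / 2)
  t_s <- radius <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - lo_off):min(n, i + hi_off)
    t_s[i] <- mean(trace$t_s[idx])
    radius[i] <- mean(trace$radius_um[idx], na.rm = TRUE)
  }
  radius[is.nan(radius)] <- NA_real_
  out <- data.frame(t_s = t_s, radius_um = trace$radius_um,
                    quality = trace$quality, smoothed_radius_um = radius)
  structure(out, class = c("obci_front_trace", "data.frame"),
            target_ph = attr(trace, "target_ph"),
            pore_radius_um = attr(trace, "pore_radius_um"))
}

#' Write a front trace as CSV
#'
#' Columns: `t_s, radius_um, quality, smoothed_radius_um`.
#'
#' @param trace An `obci_front_trace` (smoothed or not).
#' @param path Output path.
#' @param window Smoothing window used if the trace is not yet smoothed.
#' @export
write_trace_csv <- function(trace, path, window = 6) {
  if (is.null(trace$smoothed_radius_um)) trace <- smooth_trace(trace, window)
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Plot front distance versus time
#'
#' @param trace An `obci_front_trace`.
#' @param file Optional PNG path; `NULL` plots to the active device.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_front_trace <- function(trace, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(trace$t_s, trace$radius_um, pch = 16, col = "grey40",
                 xlab = "time (s)",
                 ylab = sprintf("distance of pH %.1f circle from pore (µm)",
                                attr(trace, "target_ph")),
                 ...)
  if (!is.null(trace$smoothed_radius_um))
    graphics::lines(trace$t_s, trace$smoothed_radius_um, col = "darkgreen", lwd = 2)
  invisible(trace)
}
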