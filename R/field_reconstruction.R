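#' Scalar field on the ROI pixel grid
#'
#' A thin container for a dense per-pixel map (one color channel or pH) plus a
#' validity mask marking pixels outside the interpolation hull (no data is
#' invented beyond the convex hull of the beads).
#'
#' @param values Numeric matrix (`rows x cols`).
#' @param valid Logical matrix of the same shape; defaults to finite values.
#' @param channel Label: `"r_pn"`, `"g_pn"`, `"b_pn"` or `"ph"`.
#' @return An object of class `obci_field`.
#' @export
scalar_field <- function(values, valid = NULL, channel = "value") {
  if (is.null(valid)) valid <- is.finite(values)
  stopifnot(all(dim(valid) == dim(values)))
  structure(list(values = values, valid = valid, channel = channel),
            class = "obci_field")
}

#' @export
print.obci_field <- function(x, ...) {
  cat(sprintf("obci field '%s': %d x %d, %.1f%% valid, range [%.4g, %.4g]\n",
              x$channel, nrow(x$values), ncol(x$values),
              100 * mean(x$valid),
              min(x$values[x$valid]), max(x$values[x$valid])))
  invisible(x)
}

#' Piecewise-linear (Delaunay) interpolation of scattered bead samples
#'
#' Interpolates each color channel independently over the Delaunay
#' triangulation of the bead-pixel positions: inside the convex hull each
#' pixel's value is the barycentric (piecewise-linear) interpolant of its
#' enclosing triangle's vertices; pixels outside the hull are marked invalid
#' rather than extrapolated. This is the step that fills in pixels where no
#' beads were placed.
#'
#' @param samples Data.frame with 0-based `row`, `col` and the columns named in
#'   `value_cols` (defaults to the three normalized channels).
#' @param dim Grid shape `c(rows, cols)`.
#' @param value_cols Character vector of sample columns to interpolate.
#' @return A named list of `obci_field`s, one per value column.
#' @export
delaunay_interpolate <- function(samples, dim,
                                 value_cols = c("r_pn", "g_pn", "b_pn")) {
  if (nrow(samples) < 3)
    stop("Delaunay interpolation needs at least 3 samples (got ", nrow(samples), ")")
  rows <- samples$row
  cols <- samples$col
  if (anyDuplicated(cbind(rows, cols)))
    stop("duplicate sample positions")
  out <- lapply(value_cols, function(colname) {
    z <- samples[[colname]]
    g <- tryCatch(
      interp::interp(x = cols, y = rows, z = z,
                     xo = 0:(dim[2] - 1), yo = 0:(dim[1] - 1),
                     method = "linear", output = "grid"),
      error = function(e) {
        if (grepl("collinear|on a line|linear structure|shull", conditionMessage(e),
                  ignore.case = TRUE))
          stop("Delaunay interpolation failed: samples are collinear", call. = FALSE)
        stop(e)
      })
    values <- t(g$z)  # interp returns z[x, y]; transpose to [row, col]
    scalar_field(values, channel = colname)
  })
  names(out) <- value_cols
  out
}

#' Re-normalize a recomposed color field (pixel normalization)
#'
#' Linear interpolation acts on each channel separately, so the recomposed
#' per-pixel color drifts slightly off the unit sphere. This step projects
#' every valid pixel back to unit norm and reports the size of the adjustment
#' as a QC statistic (`median_norm_deviation`): large deviations indicate that
#' neighboring beads disagree strongly in color.
#'
#' @param fields Named list of `obci_field`s `r_pn`, `g_pn`, `b_pn`.
#' @return The same list, renormalized, with attribute `qc` carrying
#'   `median_norm_deviation` and `max_norm_deviation`.
#' @export
renormalize_fields <- function(fields) {
  valid <- fields$r_pn$valid & fields$g_pn$valid & fields$b_pn$valid
  nrm <- sqrt(fields$r_pn$values^2 + fields$g_pn$values^2 + fields$b_pn$values^2)
  dev <- abs(nrm[valid] - 1)
  nrm[!valid | nrm == 0] <- 1
  for (ch in c("r_pn", "g_pn", "b_pn")) {
    fields[[ch]]$values <- fields[[ch]]$values / nrm
    fields[[ch]]$valid <- valid
  }
  attr(fields, "qc") <- list(median_norm_deviation = stats::median(dev),
                             max_norm_deviation = if (length(dev)) max(dev) else NA_real_)
  fields
}

# Annulus index (0-based) of every pixel for a given center, plus radii.
annulus_index <- function(dim, center, ring_width) {
  rr <- matrix(0:(dim[1] - 1), dim[1], dim[2])
  cc <- matrix(0:(dim[2] - 1), dim[1], dim[2], byrow = TRUE)
  r_px <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  list(k = floor(r_px / ring_width), r_px = r_px)
}

#' Radial ring averaging around the source
#'
#' Enforces the circular symmetry of transport around the pore: pixels are
#' binned into concentric annuli of `ring_width` pixels starting at the source
#' center, and each annulus is assigned the mean of the valid pixels in a
#' sliding window of `window` annuli centered on it (the default 3-annulus
#' window reproduces the "5-pixel ring with 15-pixel radially averaged
#' information" smoothing; the innermost annulus uses only itself and its
#' outer neighbor). Annuli extend to the image corners. An annulus whose
#' window holds no valid pixel inherits the nearest valid annulus value and is
#' flagged.
#'
#' With `window = 1` the operation is the pure annulus-binning projection,
#' which is idempotent; the 3-annulus window applies additional radial
#' smoothing each time it is applied.
#'
#' @param field An `obci_field` (or plain matrix).
#' @param center Source center, 0-based `(row, col)`.
#' @param ring_width Annulus width in pixels (default 5).
#' @param window Odd number of annuli averaged per output annulus (default 3).
#' @return An `obci_field` with attribute `profile`: a data.frame
#'   `annulus, r_mid_px, value, n_pixels, flagged`.
#' @export
radial_ring_average <- function(field, center, ring_width = 5, window = 3) {
  if (inherits(field, "obci_field")) {
    values <- field$values; valid <- field$valid; channel <- field$channel
  } else {
    values <- field; valid <- is.finite(field); channel <- "value"
  }
  if (ring_width < 1) stop("ring_width must be >= 1")
  if (window %% 2 != 1) stop("window must be odd")
  d <- dim(values)
  if (center[1] < 0 || center[1] > d[1] - 1 || center[2] < 0 || center[2] > d[2] - 1)
    stop("center must lie inside the grid")
  ai <- annulus_index(d, center, ring_width)
  kmax <- max(ai$k)
  k_f <- factor(ai$k[valid], levels = 0:kmax)
  sums <- tapply(values[valid], k_f, sum)
  sums[is.na(sums)] <- 0
  cnts <- as.numeric(table(k_f))
  half <- (window - 1) / 2
  # sliding-window (pixel-weighted) means over annuli; edges truncate
  wsum <- wcnt <- numeric(kmax + 1)
  for (off in -half:half) {
    src <- (0:kmax) + off
    ok <- src >= 0 & src <= kmax
    wsum[ok] <- wsum[ok] + sums[src[ok] + 1]
    wcnt[ok] <- wcnt[ok] + cnts[src[ok] + 1]
  }
  value <- ifelse(wcnt > 0, wsum / wcnt, NA_real_)
  flagged <- wcnt == 0
  if (any(flagged) && any(!flagged)) {
    good <- which(!flagged)
    for (k in which(flagged)) {
      value[k] <- value[good[which.min(abs(good - k))]]
    }
  }
  out <- matrix(value[ai$k + 1], d[1], d[2])
  profile <- data.frame(annulus = 0:kmax,
                        r_mid_px = (0:kmax + 0.5) * ring_width,
                        value = value,
                        n_pixels = cnts,
                        flagged = flagged)
  res <- scalar_field(out, valid = is.finite(out), channel = channel)
  attr(res, "profile") <- profile
  res
}

#' Field series: time-indexed scalar or color fields
#'
#' @param times Strictly increasing timestamps in seconds.
#' @param fields List (same length as `times`); each element is either an
#'   `obci_field`/matrix or a named list of them (per-channel).
#' @param center Source center, 0-based `(row, col)`.
#' @param pore_radius_px Pore radius in pixels (metadata).
#' @param um_per_px Physical pixel size.
#' @return An object of class `obci_series`.
#' @export
field_series <- function(times, fields, center = NULL, pore_radius_px = NA,
                         um_per_px = 1) {
  if (length(times) != length(fields)) stop("times and fields lengths differ")
  if (any(diff(times) <= 0)) stop("timestamps must be strictly increasing")
  structure(list(times = as.numeric(times), fields = fields, center = center,
                 pore_radius_px = pore_radius_px, um_per_px = um_per_px),
            class = "obci_series")
}

#' @export
print.obci_series <- function(x, ...) {
  cat(sprintf("obci series: %d frames, t = %g..%g s\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

blend_fields <- function(a, b, w) {
  # pixelwise (1-w)*a + w*b, recursing into per-channel lists
  if (is.list(a) && !inherits(a, "obci_field")) {
    out <- Map(blend_fields, a, b, MoreArgs = list(w = w))
    return(out)
  }
  if (inherits(a, "obci_field")) {
    scalar_field((1 - w) * a$values + w * b$values,
                 valid = a$valid & b$valid, channel = a$channel)
  } else {
    (1 - w) * a + w * b
  }
}

#' Linear interpolation of a field series in time
#'
#' Produces frames at multiples of `out_interval_s` spanning the acquired
#' range (typically 10 s output from 30 s acquisitions, for better temporal
#' continuity). Each output frame is the pixelwise linear blend of the two
#' bracketing acquired frames; frames that coincide with an acquired timestamp
#' are the original frames, unchanged. No extrapolation outside the acquired
#' span is performed.
#'
#' @param series An `obci_series` (fields may be matrices, `obci_field`s or
#'   per-channel lists).
#' @param out_interval_s Output frame interval in seconds (default 10).
#' @return A new `obci_series`.
#' @export
temporal_interpolate <- function(series, out_interval_s = 10) {
  times <- series$times
  if (length(times) < 2) stop("temporal interpolation needs at least 2 frames")
  t_out <- seq(times[1], times[length(times)], by = out_interval_s)
  fields <- lapply(t_out, function(t) {
    hit <- which(abs(times - t) < 1e-9)
    if (length(hit) == 1) return(series$fields[[hit]])
    if (t < times[1] || t > times[length(times)])
      stop("requested time ", t, " s outside the acquired span")
    i <- findInterval(t, times)
    w <- (t - times[i]) / (times[i + 1] - times[i])
    blend_fields(series$fields[[i]], series$fields[[i + 1]], w)
  })
  field_series(t_out, fields, center = series$center,
               pore_radius_px = series$pore_radius_px,
               um_per_px = series$um_per_px)
}

#' Convert a reconstructed color field to a pH field
#'
#' Applies the calibration inversion pixel by pixel to the recomposed
#' normalized color. Pixels whose color falls outside the calibrated span are
#' clamped to the range endpoint and counted in the `clamped_fraction` QC
#' attribute.
#'
#' @param fields Named list of `obci_field`s `r_pn`, `g_pn`, `b_pn`
#'   (congruent).
#' @param curve An `obci_calibration`.
#' @return An `obci_field` of pH with attributes `clamped` (logical matrix)
#'   and `clamped_fraction`.
#' @export
field_to_ph <- function(fields, curve) {
  valid <- fields$r_pn$valid & fields$g_pn$valid & fields$b_pn$valid
  d <- dim(fields$r_pn$values)
  ph <- matrix(NA_real_, d[1], d[2])
  clamped <- matrix(FALSE, d[1], d[2])
  if (any(valid)) {
    cols <- cbind(fields$r_pn$values[valid],
                  fields$g_pn$values[valid],
                  fields$b_pn$values[valid])
    res <- color_to_ph(curve, cols)
    ph[valid] <- as.numeric(res)
    clamped[valid] <- attr(res, "clamped")
  }
  out <- scalar_field(ph, valid = valid, channel = "ph")
  attr(out, "clamped") <- clamped
  attr(out, "clamped_fraction") <- if (any(valid)) mean(clamped[valid]) else NA_real_
  out
}

#' Write an annulus pH profile as CSV (`t_s, r_px, r_um, ph_mean, n_pixels`)
#'
#' @param profile Profile data.frame from [radial_ring_average()].
#' @param t Frame timestamp (seconds).
#' @param um_per_px Pixel size.
#' @param path Output path; rows are appended when the file exists.
#' @export
write_profile_csv <- function(profile, t, um_per_px, path) {
  df <- data.frame(t_s = t, r_px = profile$r_mid_px,
                   r_um = profile$r_mid_px * um_per_px,
                   ph_mean = profile$value, n_pixels = profile$n_pixels)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
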