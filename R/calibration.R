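#' Assemble calibration points
#'
#' A calibration point is the mean Pythagorean-normalized color of bead regions
#' observed at a known pH, together with its per-channel dispersion. Points are
#' typically acquired by exposing the bead membrane to buffers between pH 5.0
#' and 8.0 in 0.5-unit increments and measuring bead RGB intensities in ~10
#' regions per image.
#'
#' @param ph Known pH values (strictly inside (0, 14)).
#' @param r_pn,g_pn,b_pn Mean normalized channel intensities at each pH.
#' @param sd_r,sd_g,sd_b Per-channel standard deviations across regions.
#' @param n_regions Number of bead regions averaged per point.
#' @param direction Optional label (e.g. `"up"`/`"down"`) recording the
#'   titration direction of the calibration pass; used for the hysteresis
#'   diagnostic in [build_calibration()].
#' @return A `data.frame` of calibration points.
#' @export
calibration_points <- function(ph, r_pn, g_pn, b_pn,
                               sd_r = 0, sd_g = 0, sd_b = 0,
                               n_regions = 1L, direction = NA_character_) {
  if (any(ph <= 0 | ph >= 14)) stop("calibration pH values must lie in (0, 14)")
  if (any(c(sd_r, sd_g, sd_b) < 0)) stop("dispersions must be non-negative")
  data.frame(ph = ph, r_pn = r_pn, g_pn = g_pn, b_pn = b_pn,
             sd_r = sd_r, sd_g = sd_g, sd_b = sd_b,
             n_regions = n_regions, direction = direction,
             stringsAsFactors = FALSE)
}

inversion_values <- function(points, inversion_channel) {
  switch(inversion_channel,
    "r"   = points$r_pn,
    "g"   = points$g_pn,
    "b"   = points$b_pn,
    "r/b" = points$r_pn / points$b_pn,
    stop("unknown inversion channel: ", inversion_channel,
         " (expected 'r', 'g', 'b' or 'r/b')"))
}

#' Fit a monotone color-response-vs-pH calibration curve
#'
#' Fits a per-channel smooth map pH -> normalized intensity through the
#' calibration points and designates one channel (or the r/b ratio) as the
#' inversion channel used to convert observed colors back to pH. The default
#' model is a shape-preserving monotone piecewise-cubic interpolant
#' (Fritsch-Carlson), which reproduces every point exactly and guarantees the
#' monotonicity the inversion needs without assuming any optode response
#' theory; a 4-parameter logistic fit is available for smoother extrapolation.
#'
#' If the points contain repeated pH values (e.g. calibration passes in both
#' titration directions), the repeats are pooled by averaging and the mean
#' absolute discrepancy between directions on the inversion channel is
#' reported as the `hysteresis` diagnostic.
#'
#' @param points A data.frame as produced by [calibration_points()] (or read
#'   with [read_calibration_csv()]); at least 4 distinct pH values.
#' @param inversion_channel `"r"` (default; red is the most pH-sensitive
#'   channel), `"b"`, or the ratio `"r/b"`.
#' @param method `"spline"` (monotone interpolation, default) or `"logistic"`
#'   (4-parameter logistic per channel).
#' @return An object of class `obci_calibration`.
#' @export
build_calibration <- function(points,
                              inversion_channel = c("r", "b", "r/b", "g"),
                              method = c("spline", "logistic")) {
  inversion_channel <- match.arg(inversion_channel)
  method <- match.arg(method)
  required <- c("ph", "r_pn", "g_pn", "b_pn")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0)
    stop("calibration points missing column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- points

  # Pool repeated pH values (e.g. both titration directions) by averaging and
  # quantify the direction discrepancy as a hysteresis diagnostic.
  hysteresis <- NA_real_
  if (anyDuplicated(points$ph)) {
    dup_ph <- unique(points$ph[duplicated(points$ph)])
    v <- inversion_values(points, inversion_channel)
    gaps <- vapply(dup_ph, function(p) {
      vals <- v[points$ph == p]
      max(vals) - min(vals)
    }, numeric(1))
    hysteresis <- mean(gaps)
    agg <- stats::aggregate(points[c("r_pn", "g_pn", "b_pn")],
                            by = list(ph = points$ph), FUN = mean)
    points <- agg
  }
  points <- points[order(points$ph), , drop = FALSE]
  if (nrow(points) < 4)
    stop("at least 4 calibration points at distinct pH values are required (got ",
         nrow(points), ")")

  v <- inversion_values(points, inversion_channel)
  d <- diff(v)
  if (any(d == 0) || length(unique(sign(d))) != 1) {
    nz <- which(d != 0)
    ref <- if (length(nz) > 0) sign(d[nz[1]]) else 0
    bad <- which(d == 0 | sign(d) != ref)[1]
    stop(sprintf(
      "inversion channel '%s' is not strictly monotone across calibration points: pH %.3g (%.5g) vs pH %.3g (%.5g)",
      inversion_channel, points$ph[bad], v[bad], points$ph[bad + 1], v[bad + 1]))
  }

  channel_model <- lapply(c(r = "r_pn", g = "g_pn", b = "b_pn"), function(col) {
    fit_channel_model(points$ph, points[[col]], method)
  })
  inv_fun <- if (inversion_channel == "r/b") {
    fit_channel_model(points$ph, v, method)
  } else {
    channel_model[[substr(inversion_channel, 1, 1)]]
  }

  structure(list(
    points = points,
    raw_points = raw,
    channel_model = channel_model,
    inv_fun = inv_fun,
    inversion_channel = inversion_channel,
    method = method,
    ph_range = range(points$ph),
    increasing = d[1] > 0,
    hysteresis = hysteresis
  ), class = "obci_calibration")
}

# Monotone shape-preserving interpolant or 4PL logistic for one channel.
# Returns a function f(ph, deriv = 0) vectorized in ph.
fit_channel_model <- function(ph, value, method) {
  if (method == "spline") {
    sf <- stats::splinefun(ph, value, method = "monoH.FC")
    function(x, deriv = 0) sf(x, deriv = deriv)
  } else {
    lo <- value[which.min(ph)]; hi <- value[which.max(ph)]
    start <- list(A = lo, B = hi, m = stats::median(ph), s = 1)
    fit <- try(minpack.lm::nlsLM(
      value ~ A + (B - A) / (1 + 10^(s * (m - ph))),
      data = data.frame(ph = ph, value = value), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      # near-flat channels can defeat the logistic; fall back to the spline
      sf <- stats::splinefun(ph, value, method = "monoH.FC")
      return(function(x, deriv = 0) sf(x, deriv = deriv))
    }
    cf <- as.list(stats::coef(fit))
    function(x, deriv = 0) {
      u <- 10^(cf$s * (cf$m - x))
      if (deriv == 0) {
        cf$A + (cf$B - cf$A) / (1 + u)
      } else if (deriv == 1) {
        (cf$B - cf$A) * log(10) * cf$s * u / (1 + u)^2
      } else stop("deriv > 1 not supported")
    }
  }
}

#' Evaluate a calibration curve
#'
#' @param object An `obci_calibration` curve.
#' @param ph pH values at which to evaluate.
#' @param channel `"r"`, `"g"`, `"b"`, or `"inv"` for the inversion channel
#'   model (which may be a channel ratio).
#' @param ... Unused.
#' @return Modeled normalized intensities (or ratio values).
#' @export
predict.obci_calibration <- function(object, ph, channel = "inv", ...) {
  if (channel == "inv") object$inv_fun(ph)
  else object$channel_model[[match_channel(channel)]](ph)
}

#' @export
print.obci_calibration <- function(x, ...) {
  cat(sprintf(
    "obci calibration: %d points, pH %.2f-%.2f, inversion channel '%s' (%s, %s)\n",
    nrow(x$points), x$ph_range[1], x$ph_range[2], x$inversion_channel,
    x$method, if (x$increasing) "increasing" else "decreasing"))
  if (!is.na(x$hysteresis))
    cat(sprintf("  direction hysteresis (mean |gap| on inversion channel): %.4g\n",
                x$hysteresis))
  invisible(x)
}

# Invert inversion-channel values to pH. Vectorized: coarse bracket from a
# dense monotone grid, then Newton polishing on the smooth model. Values
# outside the calibrated span are clamped to the nearest endpoint and flagged.
invert_inversion_values <- function(curve, v) {
  lo <- curve$ph_range[1]; hi <- curve$ph_range[2]
  grid <- seq(lo, hi, length.out = 513L)
  fg <- curve$inv_fun(grid)
  v_lo <- fg[1]; v_hi <- fg[length(fg)]
  vmin <- min(v_lo, v_hi); vmax <- max(v_lo, v_hi)
  clamped <- v < vmin | v > vmax
  vc <- pmin(pmax(v, vmin), vmax)
  # monotone grid -> piecewise-linear first guess
  if (curve$increasing) {
    ph <- stats::approx(fg, grid, xout = vc, rule = 2, ties = "ordered")$y
  } else {
    ph <- stats::approx(rev(fg), rev(grid), xout = vc, rule = 2, ties = "ordered")$y
  }
  for (it in 1:4) {
    f <- curve$inv_fun(ph) - vc
    fp <- curve$inv_fun(ph, deriv = 1)
    step <- ifelse(abs(fp) > 1e-12, f / fp, 0)
    ph <- pmin(pmax(ph - step, lo), hi)
  }
  ph[clamped] <- ifelse((v[clamped] > vmax) == (curve$increasing), hi, lo)
  list(ph = ph, clamped = clamped)
}

#' Convert an observed color to pH
#'
#' Finds the unique pH within the calibrated range whose modeled
#' inversion-channel value matches the observed one (root finding on the
#' strictly monotone model). Colors whose inversion value falls outside the
#' calibrated span are assigned the nearest range endpoint and flagged: an
#' optode saturates outside its dynamic range, so clamping is informative, not
#' fatal.
#'
#' @param curve An `obci_calibration`.
#' @param color A normalized color (length-3 vector or `n x 3` matrix).
#' @return Numeric pH vector with attribute `"clamped"` (logical vector
#'   marking out-of-range observations).
#' @export
color_to_ph <- function(curve, color) {
  m <- as_color_matrix(color)
  v <- switch(curve$inversion_channel,
              "r" = m[, 1], "g" = m[, 2], "b" = m[, 3],
              "r/b" = m[, 1] / m[, 3])
  res <- invert_inversion_values(curve, v)
  structure(res$ph, clamped = res$clamped)
}

#' First-order pH resolution of a calibration
#'
#' Propagates a per-channel color noise level through the inversion channel:
#' `delta_pH = color_noise / |d model / d pH|`. The resolution is best
#' (smallest) where the response is steepest, near the inflection of the
#' sigmoidal optode response.
#'
#' @param curve An `obci_calibration`.
#' @param ph pH value(s) within the calibrated range.
#' @param color_noise Standard deviation of the normalized inversion-channel
#'   value (dimensionless), > 0.
#' @return Estimated pH resolution (same length as `ph`); `Inf` where the
#'   modeled slope vanishes.
#' @export
estimate_resolution <- function(curve, ph, color_noise) {
  if (any(color_noise <= 0)) stop("color_noise must be > 0")
  if (any(ph < curve$ph_range[1] | ph > curve$ph_range[2]))
    stop("ph outside the calibrated range")
  slope <- abs(curve$inv_fun(ph, deriv = 1))
  out <- ifelse(slope > 0, color_noise / slope, Inf)
  if (any(!is.finite(out)))
    warning("zero response slope at some pH values: resolution is unbounded there")
  out
}

#' Read / write calibration points as CSV
#'
#' The CSV schema is `ph, r_pn, g_pn, b_pn, sd_r, sd_g, sd_b, n_regions`
#' (dispersion and count columns optional, `direction` optional).
#'
#' @param path File path.
#' @return `read_calibration_csv()` returns a calibration-point data.frame.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ph", "r_pn", "g_pn", "b_pn")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("calibration CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("sd_r", "sd_g", "sd_b")) if (is.null(df[[col]])) df[[col]] <- 0
  if (is.null(df$n_regions)) df$n_regions <- 1L
  df
}

#' @param points Calibration-point data.frame.
#' @rdname read_calibration_csv
#' @export
write_calibration_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a calibration curve to JSON (and back)
#'
#' The JSON stores the pooled calibration points plus the fit settings; the
#' curve is rebuilt deterministically on load, so the file is a portable,
#' human-readable record of the calibration.
#'
#' @param curve An `obci_calibration`.
#' @param path File path.
#' @export
write_calibration_json <- function(curve, path) {
  obj <- list(
    points = curve$points,
    settings = list(inversion_channel = curve$inversion_channel,
                    method = curve$method),
    hysteresis = curve$hysteresis
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  curve <- build_calibration(obj$points,
                             inversion_channel = obj$settings$inversion_channel,
                             method = obj$settings$method)
  if (!is.null(obj$hysteresis)) curve$hysteresis <- obj$hysteresis
  curve
}

#' Green-channel drift QC
#'
#' The green channel responds only weakly to pH and can serve as an internal
#' reference: systematic drift of the mean normalized green intensity across
#' frames indicates illumination or focus problems rather than chemistry.
#' Frames whose mean G_pn deviates from the median by more than
#' `nsigma` robust standard deviations are flagged.
#'
#' @param mean_g Per-frame mean normalized green intensity.
#' @param nsigma Flagging threshold in robust SD units (default 3).
#' @return Logical vector of flagged frames.
#' @export
qc_green_drift <- function(mean_g, nsigma = 3) {
  med <- stats::median(mean_g)
  s <- stats::mad(mean_g)
  if (s == 0) return(rep(FALSE, length(mean_g)))
  abs(mean_g - med) > nsigma * s
}
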