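#' Pythagorean (unit-norm) normalization of RGB colors
#'
#' Divides each RGB component by the Euclidean norm of the RGB vector, so the
#' normalized color is a unit vector on the positive eighth of the unit sphere.
#' The resulting color is independent of the illumination intensity: scaling
#' all three channels by the same positive factor leaves it unchanged, which is
#' what makes a reflectance optode calibration transferable between frames.
#'
#' @param x A length-3 numeric vector `c(r, g, b)` or an `n x 3` matrix (one
#'   color per row). Components must be non-negative reflectance intensities
#'   (8-bit counts or floats); the scale is irrelevant.
#' @return An object of the same shape with each row scaled to unit Euclidean
#'   norm.
#' @examples
#' pythagorean_normalize(c(3, 0, 4))   # (0.6, 0, 0.8)
#' pythagorean_normalize(c(10, 10, 10))
#' @export
pythagorean_normalize <- function(x) {
  m <- as_color_matrix(x)
  if (any(m < 0)) stop("RGB components must be non-negative")
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    stop("all-zero RGB triplet: color direction is undefined")
  }
  out <- m / nrm
  restore_color_shape(out, x)
}

#' Sum normalization of RGB colors
#'
#' Divides each component by the channel sum (`X / (R + G + B)`), the more
#' common chromaticity normalization. Provided for comparison with
#' [pythagorean_normalize()]; the resulting 3-vector has unit *sum* but its
#' Euclidean length varies with the color, so it is not a point on the unit
#' sphere. Pythagorean normalization is the default throughout the package.
#'
#' @inheritParams pythagorean_normalize
#' @return Same shape as the input, rows scaled to unit sum.
#' @export
sum_normalize <- function(x) {
  m <- as_color_matrix(x)
  if (any(m < 0)) stop("RGB components must be non-negative")
  s <- rowSums(m)
  if (any(s == 0)) stop("all-zero RGB triplet: color direction is undefined")
  restore_color_shape(m / s, x)
}

#' Ratio of two channels of a normalized color
#'
#' After normalization only two independent color variables remain, and the
#' ratio of two channels (for instance red over blue) condenses them into one
#' scalar that can be more pH-sensitive than either channel alone. The ratio is
#' deliberately not bounded to `[0, 1]`.
#'
#' @param x A normalized color (length-3 vector or `n x 3` matrix).
#' @param num,den Channel identifiers: `"r"`, `"g"` or `"b"`.
#' @return Numeric vector of ratios `num / den`.
#' @examples
#' channel_ratio(pythagorean_normalize(c(3, 0, 4)), "r", "b")  # 0.75
#' @export
channel_ratio <- function(x, num = "r", den = "b") {
  m <- as_color_matrix(x)
  i <- match_channel(num)
  j <- match_channel(den)
  if (any(m[, j] == 0)) stop("channel ratio undefined: denominator channel is zero")
  unname(m[, i] / m[, j])
}

match_channel <- function(ch) {
  idx <- match(tolower(ch), c("r", "g", "b"))
  if (is.na(idx)) stop("unknown channel: ", ch, " (expected 'r', 'g' or 'b')")
  idx
}

# Accept a length-3 vector, n x 3 matrix or data.frame; always return a matrix.
as_color_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("a color must have exactly 3 components (r, g, b)")
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  if (ncol(x) != 3L) stop("color matrix must have 3 columns (r, g, b)")
  storage.mode(x) <- "double"
  x
}

restore_color_shape <- function(m, template) {
  if (is.null(dim(template))) as.numeric(m[1L, ]) else m
}
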