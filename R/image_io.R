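#' Read an RGB image (PNG or TIFF)
#'
#' Returns the image as an `rows x cols x 3` numeric array of intensities on
#' the 0-255 scale, regardless of the file's bit depth. Grayscale files are
#' replicated across the three channels; an alpha channel, if present, is
#' dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric array `rows x cols x 3`, values in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "png" = png::readPNG(path),
    "tif" = ,
    "tiff" = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expected png or tiff)"))
  to_rgb255(img)
}

to_rgb255 <- function(img) {
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  nc <- dim(img)[3]
  if (nc == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Read a time-ordered frame stack
#'
#' Accepts either a directory of numbered PNG/TIFF frames (sorted by file
#' name), an explicit vector of file paths, or a single multi-frame TIFF.
#' Timestamps are `(frame index - 1) * interval_s` unless given explicitly.
#'
#' @param x Directory, vector of file paths, or one multi-frame TIFF path.
#' @param interval_s Acquisition interval in seconds (default 30).
#' @param times Optional explicit timestamps (seconds), overriding
#'   `interval_s`.
#' @return A list with elements `images` (list of `rows x cols x 3` arrays,
#'   0-255) and `times` (seconds).
#' @export
read_frames <- function(x, interval_s = 30, times = NULL) {
  if (length(x) == 1L && dir.exists(x)) {
    x <- sort(list.files(x, pattern = "\\.(png|tif|tiff)$",
                         ignore.case = TRUE, full.names = TRUE))
    if (length(x) == 0L) stop("no PNG/TIFF frames found in directory")
  }
  if (length(x) == 1L && grepl("\\.tiff?$", x, ignore.case = TRUE)) {
    raw <- tiff::readTIFF(x, all = TRUE)
    images <- lapply(raw, to_rgb255)
  } else {
    images <- lapply(x, read_image)
  }
  if (is.null(times)) times <- (seq_along(images) - 1) * interval_s
  if (length(times) != length(images))
    stop("length of times does not match number of frames")
  list(images = images, times = as.numeric(times))
}

#' Write an RGB image (0-255) as 8-bit PNG
#'
#' @param img `rows x cols x 3` array on the 0-255 scale.
#' @param path Output path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

#' Write a bead mask as a single-channel PNG (bead = 255, background = 0)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a pH (or other bounded scalar) field as 32-bit TIFF
#'
#' Values are stored as 32-bit samples of `value / scale` (default scale 14,
#' covering the pH range with ~3e-9 pH quantization); invalid (`NA`/`NaN`)
#' pixels are stored as 0, which is outside any physical pH.
#'
#' @param values Numeric matrix in `[0, scale]`.
#' @param path Output path.
#' @param scale Full-scale value (default 14).
#' @export
write_field_tiff <- function(values, path, scale = 14) {
  x <- values / scale
  x[!is.finite(x)] <- 0
  tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  invisible(path)
}

#' Read a scalar field written by [write_field_tiff()]
#'
#' @param path File path.
#' @param scale Full-scale value used when writing (default 14).
#' @return Numeric matrix (`NaN` marks invalid pixels).
#' @export
read_field_tiff <- function(path, scale = 14) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x <- x * scale
  x[x == 0] <- NaN
  x
}
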