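#' Per-pixel bead score
#'
#' Beads are strongly colored (blue to orange) and darker than the near-white
#' substrate, so each pixel is scored by its chroma (`max(R,G,B) - min(R,G,B)`)
#' optionally combined with darkness (`255 - min(R,G,B)`). The pure-chroma
#' score is invariant to global intensity scaling of the image, matching the
#' illumination independence of normalized color; the combined score separates
#' beads from substrate more aggressively and is the default.
#'
#' @param image `rows x cols x 3` array, 0-255 scale.
#' @param method `"chroma_darkness"` (default) or `"chroma"`.
#' @return Numeric score matrix (higher = more bead-like).
#' @export
bead_score <- function(image, method = c("chroma_darkness", "chroma")) {
  method <- match.arg(method)
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  if (method == "chroma") mx - mn else (mx - mn) + (255 - mn)
}

#' Threshold an image into a bead mask
#'
#' Builds the binary bead mask used by the interpolation stage: bead pixels
#' are `TRUE` (the conventional "white = 1"), substrate pixels `FALSE`. The
#' threshold on the bead score is chosen automatically by Otsu's method unless
#' a manual threshold is supplied.
#'
#' @param image `rows x cols x 3` array, 0-255 scale, on a light background.
#' @param threshold Optional fixed score threshold; `NULL` (default) uses Otsu.
#' @param method Score method, see [bead_score()].
#' @return Logical matrix with attributes `threshold` and `method`. Errors if
#'   the mask comes out empty (advising a threshold adjustment).
#' @export
build_mask <- function(image, threshold = NULL,
                       method = c("chroma_darkness", "chroma")) {
  method <- match.arg(method)
  score <- bead_score(image, method)
  if (max(score) - min(score) < 1e-9)
    stop("empty bead mask: image has no contrast in the bead score; adjust the threshold settings")
  if (is.null(threshold)) {
    scale <- max(score)
    threshold <- EBImage::otsu(score / scale, range = c(0, 1), levels = 256L) * scale
  }
  mask <- score > threshold
  if (!any(mask))
    stop("empty bead mask: no pixel exceeds the threshold (", signif(threshold, 4),
         "); adjust the threshold settings")
  structure(mask, threshold = threshold, method = method)
}

#' Extract per-pixel bead color samples
#'
#' One sample is taken per masked pixel (pixel-level sampling: the
#' interpolation uses every bead pixel, not per-bead centroids), with the
#' color taken from the unprocessed image and Pythagorean-normalized.
#' Positions follow the package convention: 0-based `(row, col)`, origin at
#' the top-left; physical position is pixel index times micrometres per pixel.
#'
#' @param image `rows x cols x 3` array, 0-255 scale.
#' @param mask Logical bead mask of the same shape.
#' @param t Frame timestamp in seconds.
#' @param per_bead If `TRUE`, aggregate connected components to their centroid
#'   with the mean component color instead of per-pixel samples.
#' @return A data.frame `t_s, row, col, r_pn, g_pn, b_pn`.
#' @export
extract_samples <- function(image, mask, t = 0, per_bead = FALSE) {
  if (!all(dim(mask) == dim(image)[1:2]))
    stop("mask shape does not match image")
  if (!any(mask)) stop("mask is empty: no bead pixels to sample")
  idx <- which(mask, arr.ind = TRUE)
  raw <- cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  if (per_bead) {
    lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
    comp <- lab[mask]
    raw <- apply(raw, 2, function(ch) tapply(ch, comp, mean))
    rows <- tapply(idx[, 1], comp, mean)
    cols <- tapply(idx[, 2], comp, mean)
    idx <- cbind(rows, cols)
    raw <- matrix(raw, ncol = 3)
  }
  nc <- pythagorean_normalize(raw)
  data.frame(t_s = t, row = idx[, 1] - 1, col = idx[, 2] - 1,
             r_pn = nc[, 1], g_pn = nc[, 2], b_pn = nc[, 3])
}

jaccard_index <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

#' Consensus mask and drift report across frames
#'
#' Beads are immobilized and should stay put: the consensus mask keeps pixels
#' present in at least half of the per-frame masks, and frames whose Jaccard
#' similarity with the consensus falls below `flag_below` are flagged as
#' possible bead movement or focus loss. The consensus mask is the one applied
#' to every frame of an experiment.
#'
#' @param masks List of >= 2 logical masks from the same run.
#' @param flag_below Jaccard threshold below which a frame is flagged
#'   (default 0.8).
#' @return A list: `consensus` (logical matrix), `jaccard` (per frame),
#'   `flagged` (integer indices of suspect frames).
#' @export
mask_consistency <- function(masks, flag_below = 0.8) {
  if (length(masks) < 2) stop("need at least 2 masks")
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) all(dim(m) == d), logical(1))))
    stop("masks must all have the same shape")
  acc <- Reduce(`+`, lapply(masks, function(m) matrix(as.integer(m), d[1], d[2])))
  consensus <- acc >= length(masks) / 2
  jac <- vapply(masks, jaccard_index, numeric(1), b = consensus)
  list(consensus = consensus, jaccard = jac, flagged = which(jac < flag_below))
}

#' Write bead samples as CSV (`t_s, row, col, r_pn, g_pn, b_pn`)
#'
#' @param samples Sample data.frame from [extract_samples()].
#' @param path Output path.
#' @export
write_samples_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
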