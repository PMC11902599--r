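# Spectral-channel synthesis: single-channel intensity frames, grayscale and
# excess-green (ExG) combination, detector normalization, and bicubic
# digital upsampling.

#' Single-channel intensity image
#'
#' A raster of non-negative intensity counts bounded by its bit depth, the
#' unit every camera frame enters the pipeline as.  Pixels are indexed with
#' a 0-based `(u, v)` convention: `u` is the column, `v` the row, origin at
#' the top-left.
#'
#' @param pixels Numeric matrix of counts (rows = image height).
#' @param bit_depth Either 8 or 16.
#' @return An `intensity_image`: the matrix with a `bit_depth` attribute.
#' @export
intensity_image <- function(pixels, bit_depth = 8L) {
  pixels <- as.matrix(pixels)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("image must be at least 1x1")
  if (anyNA(pixels)) stop("image contains missing values")
  mx <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > mx)
    stop("intensity counts must lie in [0, 2^bit_depth - 1]")
  structure(pixels, bit_depth = as.integer(bit_depth), class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image %dx%d, %d-bit, range [%g, %g]>\n",
              nrow(x), ncol(x), attr(x, "bit_depth"), min(x), max(x)))
  invisible(x)
}

bit_depth_of <- function(x) {
  bd <- attr(x, "bit_depth")
  if (is.null(bd)) 8L else as.integer(bd)
}

#' Per-view bundle of spectral frames
#'
#' Holds the red, green and blue filter frames of one turntable view, plus
#' (optionally) the green-filter frame captured under 365 nm UV excitation,
#' whose signal is UV-induced blue-green fluorescence.
#'
#' @param red,green,blue `intensity_image` frames of identical size.
#' @param uv_green Optional UV-excited green-filter frame (same size).
#' @param view_angle Turntable angle of this view in degrees, in `[0, 360)`.
#' @return A `spectral_frames` object.
#' @export
spectral_frames <- function(red, green, blue, uv_green = NULL, view_angle = 0) {
  frames <- list(red = red, green = green, blue = blue)
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("red, green and blue frames must share the same dimensions")
  if (!is.null(uv_green) && !identical(dim(uv_green), dims[[1]]))
    stop("uv_green frame must match the structural frame dimensions")
  if (view_angle < 0 || view_angle >= 360) stop("view_angle must be in [0, 360)")
  structure(list(red = red, green = green, blue = blue, uv_green = uv_green,
                 view_angle = view_angle),
            class = "spectral_frames")
}

#' @export
print.spectral_frames <- function(x, ...) {
  cat(sprintf("<spectral_frames %dx%d at %g deg%s>\n", nrow(x$red), ncol(x$red),
              x$view_angle, if (is.null(x$uv_green)) "" else " + UV green"))
  invisible(x)
}

#' Signed channel image
#'
#' A derived channel (grayscale, ExG, or a raw filter channel promoted to a
#' common representation).  ExG values are kept signed and full-range; no
#' clipping is applied before explicit normalization.
#'
#' @param pixels Numeric matrix, possibly signed.
#' @param kind One of `"gray"`, `"exg"`, `"red"`, `"green"`, `"blue"`.
#' @param bit_depth Bit depth of the source frames (bounds the value range).
#' @export
channel_image <- function(pixels, kind, bit_depth = 8L) {
  kind <- match.arg(kind, c("gray", "exg", "red", "green", "blue"))
  mx <- 2^bit_depth - 1
  rng <- if (kind == "exg") c(-2 * mx, 2 * mx) else c(0, mx)
  if (min(pixels) < rng[1] || max(pixels) > rng[2])
    stop(sprintf("%s channel values out of range [%g, %g]", kind, rng[1], rng[2]))
  structure(as.matrix(pixels), channel_kind = kind,
            bit_depth = as.integer(bit_depth), class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image %s %dx%d, range [%g, %g]>\n",
              attr(x, "channel_kind"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

check_frames <- function(frames) {
  if (!inherits(frames, "spectral_frames"))
    stop("expected a spectral_frames object")
  frames
}

#' Grayscale channel: unweighted mean of R, G and B
#'
#' The per-pixel arithmetic mean of the three filter frames (no luminance
#' weighting).
#'
#' @param frames A [spectral_frames()] bundle.
#' @return A `channel_image` of kind `"gray"`.
#' @export
to_gray <- function(frames) {
  check_frames(frames)
  m <- (unclass(frames$red) + unclass(frames$green) + unclass(frames$blue)) / 3
  channel_image(m, "gray", bit_depth_of(frames$red))
}

#' Excess-green vegetation index
#'
#' Computes `ExG = 2 G - R - B` per pixel.  ExG amplifies the contrast of
#' green plant tissue against background and cancels achromatic components
#' (equal contributions to R, G and B) exactly, which is why keypoint
#' detection is run on this channel.  Values are signed and unclipped.
#'
#' @param frames A [spectral_frames()] bundle.
#' @return A `channel_image` of kind `"exg"`.
#' @export
compute_exg <- function(frames) {
  check_frames(frames)
  m <- 2 * unclass(frames$green) - unclass(frames$red) - unclass(frames$blue)
  channel_image(m, "exg", bit_depth_of(frames$red))
}

#' Extract a named channel from a frame set
#'
#' @param frames A [spectral_frames()] bundle.
#' @param channel `"red"`, `"green"`, `"blue"`, `"gray"` or `"exg"`.
#' @export
get_channel <- function(frames, channel = c("exg", "gray", "red", "green", "blue")) {
  channel <- match.arg(channel)
  check_frames(frames)
  switch(channel,
         exg = compute_exg(frames),
         gray = to_gray(frames),
         channel_image(unclass(frames[[channel]]), channel,
                       bit_depth_of(frames[[channel]])))
}

#' Rescale a signed channel for keypoint detection
#'
#' Affine min-max rescale to 8-bit `[0, 255]`, rounded to integers.  A
#' constant image maps to all zeros.  Keypoint detectors need bounded
#' non-negative input and the contrast ordering of the source channel is
#' preserved by the affine map.
#'
#' @param channel A `channel_image` (or `intensity_image`).
#' @return An 8-bit [intensity_image()].
#' @export
normalize_for_detection <- function(channel) {
  m <- unclass(channel)
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(intensity_image(matrix(0, nrow(m), ncol(m)), 8L))
  intensity_image(round(255 * (m - lo) / (hi - lo)), 8L)
}

#' Digitally upsample an image with bicubic interpolation
#'
#' Enlarges the frame by an integer factor using Catmull-Rom bicubic
#' convolution, the digital upsampling step that raises the number of
#' detectable keypoints (1080x1440 at factor 5 gives the 5400x7200 format).
#' Output counts are clipped to the source bit-depth range and rounded.
#'
#' @param image An [intensity_image()].
#' @param factor Integer `>= 1`.
#' @return An [intensity_image()] with `factor`-times larger dimensions.
#' @export
upsample <- function(image, factor) {
  if (length(factor) != 1 || is.na(factor) || factor < 1 || factor != round(factor))
    stop("factor must be a single integer >= 1")
  factor <- as.integer(factor)
  bd <- bit_depth_of(image)
  if (factor == 1L) return(intensity_image(unclass(image), bd))
  m <- cpp_resize_bicubic(unclass(image), nrow(image) * factor,
                          ncol(image) * factor, 0, 2^bd - 1)
  intensity_image(round(m), bd)
}
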