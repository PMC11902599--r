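# Readers for single-channel PNG/TIFF frames and the PLY point-cloud writer.

#' Read a single-channel PNG or TIFF frame
#'
#' @param path File path; `.png`, `.tif` or `.tiff`.
#' @param bit_depth Bit depth the counts are expressed in (8 or 16).
#' @return An [intensity_image()].
#' @export
read_frame <- function(path, bit_depth = 8L) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1 && !all(img[, , 1] == img[, , 2]))
      stop("expected a single-channel image: ", path)
    img <- img[, , 1]
  }
  intensity_image(round(img * (2^bit_depth - 1)), bit_depth)
}

#' Read a spectral frame set from a directory
#'
#' Files are located by substituting `{angle}` and `{channel}` into
#' `pattern`; the default layout is `{angle}_{channel}.png` with channels
#' `R`, `G`, `B` and (optionally) `UVG`.
#'
#' @param dir Directory holding the frames.
#' @param angle Angle label used in the file names (e.g. `"000"`).
#' @param pattern File-name pattern with `{angle}` and `{channel}`.
#' @param channels Named mapping from slot to channel label.
#' @param bit_depth Bit depth of the frames.
#' @param view_angle Numeric view angle stored on the frame set; defaults
#'   to `as.numeric(angle)` when that parses.
#' @return A [spectral_frames()] bundle.
#' @export
read_frameset <- function(dir, angle, pattern = "{angle}_{channel}.png",
                          channels = c(red = "R", green = "G", blue = "B",
                                       uv_green = "UVG"),
                          bit_depth = 8L, view_angle = NULL) {
  fname <- function(ch) {
    f <- gsub("{angle}", angle, pattern, fixed = TRUE)
    file.path(dir, gsub("{channel}", ch, f, fixed = TRUE))
  }
  need <- function(slot) {
    p <- fname(channels[[slot]])
    if (!file.exists(p)) stop("missing frame: ", p)
    read_frame(p, bit_depth)
  }
  uvp <- if ("uv_green" %in% names(channels)) fname(channels[["uv_green"]]) else ""
  if (is.null(view_angle)) {
    view_angle <- suppressWarnings(as.numeric(angle))
    if (is.na(view_angle)) view_angle <- 0
  }
  spectral_frames(red = need("red"), green = need("green"), blue = need("blue"),
                  uv_green = if (nzchar(uvp) && file.exists(uvp))
                    read_frame(uvp, bit_depth) else NULL,
                  view_angle = view_angle %% 360)
}

#' Write a point cloud to PLY
#'
#' Vertices carry `x`, `y`, `z` and `intensity` as 32-bit floats and
#' `disease` as an unsigned char (0/1).  ASCII by default; binary
#' little-endian on request.
#'
#' @param cloud A `plant_cloud`.
#' @param path Output file.
#' @param binary Write `binary_little_endian` instead of ASCII.
#' @export
write_ply <- function(cloud, path, binary = FALSE) {
  n <- nrow(cloud)
  inten <- ifelse(is.na(cloud$intensity), 0, cloud$intensity)
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              "comment turntable structure-from-motion plant point cloud",
              sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              "property float intensity", "property uchar disease",
              "end_header")
  if (!binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    if (n > 0)
      writeLines(sprintf("%.8g %.8g %.8g %.8g %d", cloud$X, cloud$Y, cloud$Z,
                         inten, as.integer(cloud$disease)), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    if (n > 0) {
      floats <- writeBin(as.numeric(rbind(cloud$X, cloud$Y, cloud$Z, inten)),
                         raw(), size = 4, endian = "little")
      rec <- rbind(matrix(floats, nrow = 16), matrix(as.raw(cloud$disease), 1))
      writeBin(as.vector(rec), con)
    }
  }
  invisible(path)
}
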