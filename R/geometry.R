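# Camera model: intrinsics, the 4x4 perspective (Q) matrix, homogeneous
# reprojection of disparity samples to world coordinates, and the
# sparse-to-dense surface step.

#' Camera intrinsics
#'
#' The parameters of the pinhole model the reconstruction needs: focal
#' length `f` (mm), pixel densities `ku`, `kv` (pixels per mm; the
#' reciprocal of the pixel pitch), principal point `(u0, v0)` (pixels), and
#' the dimensionless reprojection scale factor `s` entering the Q matrix.
#'
#' @param f Focal length in mm.
#' @param ku,kv Pixels per mm along u and v (square pixels give `ku == kv`).
#' @param u0,v0 Principal point in pixels.
#' @param s Reprojection scale factor (calibrated; default 0.02).
#' @export
camera_intrinsics <- function(f, ku, kv = ku, u0, v0, s = 0.02) {
  if (f <= 0 || ku <= 0 || kv <= 0) stop("f, ku and kv must be positive")
  if (s <= 0) stop("s must be positive")
  structure(list(f = f, ku = ku, kv = kv, u0 = u0, v0 = v0, s = s),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf(
    "<camera_intrinsics f=%g mm, ku=%.4g px/mm, kv=%.4g px/mm, pp=(%g, %g), s=%g>\n",
    x$f, x$ku, x$kv, x$u0, x$v0, x$s))
  invisible(x)
}

#' Intrinsics of the reference turntable camera
#'
#' The 1440x1080 monochrome camera with 3.45 um square pixels behind an
#' 8 mm objective: `ku = kv = 1/0.00345` px/mm, principal point at the
#' frame centre, `s = 0.02`.
#'
#' @param width,height Sensor format in pixels.
#' @export
default_intrinsics <- function(width = 1440L, height = 1080L) {
  camera_intrinsics(f = 8, ku = 1 / 0.00345, kv = 1 / 0.00345,
                    u0 = width / 2, v0 = height / 2, s = 0.02)
}

#' Build the 4x4 perspective transformation matrix Q
#'
#' `Q` maps a pixel-plus-inverse-disparity column `[u, v, 1/d, 1]` to
#' homogeneous world coordinates.  Its rows are exactly
#' `[1, 0, 0, -u0]`, `[0, -1, 0, v0]`, `[0, 0, s*f*ku, 0]`, `[0, 0, 0, 1]`:
#' the `-1` flips the downward image v axis so world Y points up, and the
#' depth row uses only `ku` (square pixels make the asymmetry immaterial).
#'
#' @param intr A [camera_intrinsics()].
#' @return A `q_matrix` (4x4 numeric matrix with the intrinsics attached).
#' @export
build_Q <- function(intr) {
  if (!inherits(intr, "camera_intrinsics")) stop("expected camera_intrinsics")
  Q <- matrix(c(1, 0, 0, -intr$u0,
                0, -1, 0, intr$v0,
                0, 0, intr$s * intr$f * intr$ku, 0,
                0, 0, 0, 1), 4, 4, byrow = TRUE)
  structure(Q, intrinsics = intr, class = c("q_matrix", "matrix", "array"))
}

#' Reproject pixel + disparity samples to world coordinates
#'
#' Multiplies `Q` by the homogeneous column `[u, v, 1/d, 1]` and divides by
#' the homogeneous scale `W` to obtain `[X, Y, Z]`.  Depth is inversely
#' proportional to disparity: `Z = s*f*ku / d`.
#'
#' @param u,v Pixel coordinates (0-based, u = column, v = row); vectors.
#' @param d Disparities in pixels; must all be `> 0`.
#' @param Q A `q_matrix` from [build_Q()].
#' @return A data frame with columns `X`, `Y`, `Z`.
#' @export
reproject_point <- function(u, v, d, Q) {
  if (any(d <= 0)) stop("disparities must be strictly positive")
  P <- unclass(Q) %*% rbind(u, v, 1 / d, 1)
  data.frame(X = P[1, ] / P[4, ], Y = P[2, ] / P[4, ], Z = P[3, ] / P[4, ])
}

new_plant_cloud <- function(df, Q = NULL, image_shape = NULL, world_scale = 1) {
  structure(df, q_matrix = Q, image_shape = image_shape,
            world_scale = world_scale, class = c("plant_cloud", "data.frame"))
}

#' @export
print.plant_cloud <- function(x, ...) {
  nd <- sum(x$disease)
  cat(sprintf("<plant_cloud: %d points%s, Z in [%g, %g]>\n", nrow(x),
              if (nd > 0) sprintf(" (%d disease-flagged)", nd) else "",
              if (nrow(x)) min(x$Z) else NA, if (nrow(x)) max(x$Z) else NA))
  invisible(x)
}

#' Reproject a disparity field into a sparse plant point cloud
#'
#' One cloud point per disparity sample; the channel intensity (normally
#' ExG) is sampled at the source pixel by nearest neighbour; disease flags
#' start all `FALSE`.
#'
#' @param field A `disparity_field` from [compute_disparity()].
#' @param Q A `q_matrix`.
#' @param intensity_image A `channel_image` (or matrix) aligned with the
#'   reference view, sampled per point.
#' @param world_scale Single multiplicative factor applied to `X`, `Y`, `Z`
#'   to express the cloud in physical units (mm).
#' @return A `plant_cloud` data frame: `X`, `Y`, `Z`, `intensity`,
#'   `disease`, `u`, `v`.
#' @export
reproject_field <- function(field, Q, intensity_image, world_scale = 1) {
  shape <- dim(intensity_image)
  if (nrow(field) == 0) {
    warning("empty disparity field: returning an empty cloud")
    return(new_plant_cloud(
      data.frame(X = numeric(0), Y = numeric(0), Z = numeric(0),
                 intensity = numeric(0), disease = logical(0),
                 u = numeric(0), v = numeric(0)),
      Q, shape, world_scale))
  }
  xyz <- reproject_point(field$u, field$v, field$d, Q)
  ri <- pmin(pmax(round(field$v) + 1, 1), shape[1])
  ci <- pmin(pmax(round(field$u) + 1, 1), shape[2])
  inten <- unclass(intensity_image)[cbind(ri, ci)]
  new_plant_cloud(
    data.frame(X = xyz$X * world_scale, Y = xyz$Y * world_scale,
               Z = xyz$Z * world_scale, intensity = inten,
               disease = FALSE, u = field$u, v = field$v),
    Q, shape, world_scale)
}

#' Plant mask from an ExG channel
#'
#' Pixels whose lightly smoothed ExG value exceeds a small positive margin.
#' The margin (default 5 counts) sits above the sensor-noise floor of the
#' ExG combination: with zero-mean noise the background ExG distribution is
#' symmetric about zero, so a strict `> 0` rule would admit about half the
#' background.
#'
#' @param exg A `channel_image` of kind `"exg"`.
#' @param min_exg Threshold in counts (default 5).
#' @param smooth_sigma Gaussian pre-smoothing in pixels (0 disables).
#' @return A logical matrix, `TRUE` on plant.
#' @export
plant_mask <- function(exg, min_exg = 5, smooth_sigma = 1) {
  m <- unclass(exg)
  if (smooth_sigma > 0) m <- cpp_gaussian_blur(m, smooth_sigma)
  m > min_exg
}

#' Densify a sparse cloud over the plant mask
#'
#' Produces one point per masked pixel with depth interpolated from the
#' sparse samples over the image plane: piecewise-linear (barycentric over
#' a Delaunay triangulation of the sample pixels) inside the convex hull of
#' the samples, nearest-sample depth outside it.  `method = "nearest"` uses
#' nearest-sample depth everywhere.  With fewer than 3 samples the linear
#' method falls back to nearest with a warning.
#'
#' @param cloud A sparse `plant_cloud` from [reproject_field()].
#' @param plant_mask Logical matrix (native image grid), `TRUE` where a
#'   dense point is wanted.
#' @param method `"linear"` (default) or `"nearest"`.
#' @param intensity_image Optional channel image sampled per dense pixel.
#' @return A dense `plant_cloud` with one point per masked pixel.
#' @export
densify <- function(cloud, plant_mask, method = c("linear", "nearest"),
                    intensity_image = NULL) {
  method <- match.arg(method)
  if (nrow(cloud) == 0) stop("cannot densify an empty cloud")
  if (method == "linear" && nrow(cloud) < 3) {
    warning("fewer than 3 samples: falling back to nearest-neighbour depth")
    method <- "nearest"
  }
  Q <- attr(cloud, "q_matrix")
  if (is.null(Q)) stop("cloud carries no q_matrix attribute")
  intr <- attr(Q, "intrinsics")
  ws <- attr(cloud, "world_scale")
  if (is.null(ws)) ws <- 1
  dense_z <- cpp_densify(cloud$u, cloud$v, cloud$Z, plant_mask,
                         if (method == "linear") 1L else 0L)
  idx <- which(!is.na(dense_z), arr.ind = TRUE)
  if (nrow(idx) == 0) stop("plant mask selected no pixels")
  u <- idx[, 2] - 1
  v <- idx[, 1] - 1
  inten <- if (is.null(intensity_image)) NA_real_ else
    unclass(intensity_image)[idx]
  new_plant_cloud(
    data.frame(X = (u - intr$u0) * ws, Y = (intr$v0 - v) * ws,
               Z = dense_z[idx], intensity = inten, disease = FALSE,
               u = u, v = v),
    Q, dim(plant_mask), ws)
}
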