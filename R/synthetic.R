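# Ground-truth scene generator: a textured plant-like surface rendered from
# pinhole viewpoints with known depth, known correspondences, and an
# injected fluorescence patch, so every pipeline stage is testable without
# camera data.

norm01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(m * 0)
  (m - lo) / (hi - lo)
}

smooth_noise <- function(h, w, sigma) {
  m <- cpp_gaussian_blur(matrix(rnorm(h * w), h, w), sigma)
  m / max(abs(m), 1e-12)  # band-limited speckle scaled to [-1, 1]
}

#' Generate a synthetic plant scene with ground truth
#'
#' The surface is parameterized over the reference-view pixel grid: a
#' smooth bump field (a blurred mixture of random blobs) raises "leaves"
#' towards the camera above a flat background plane at the far end of
#' `depth_range`.  The reflectance texture carries band-limited speckle so
#' keypoint detectors find features; green reflectance dominates red and
#' blue inside the leaf mask (ExG > 0 on the plant) while the background is
#' achromatic (ExG = 0 there).  Frames additionally receive a smooth
#' multiplicative illumination field and a smooth *additive achromatic*
#' ambient/glare field; the additive term cancels exactly in ExG, which is
#' the constructed reason the ExG channel shows the highest leaf texture
#' contrast of all channels.  A fluorescence patch covering a requested
#' fraction of the leaf mask is injected for the UV frame.
#'
#' @param width,height Frame size in pixels.
#' @param depth_range `c(near, far)` camera-distance range in world units;
#'   the background plane sits at `far`.
#' @param texture_grain Speckle correlation length in pixels.
#' @param n_blobs Number of leaf blobs.
#' @param patch_fraction Fraction of the leaf mask covered by the
#'   fluorescence patch (0 disables the patch).
#' @param patch_aspect Horizontal/vertical aspect ratio of the patch.
#' @param patch_level Patch emission in counts (must exceed the disease
#'   threshold; default 200 vs. the 110-count threshold).
#' @param uv_background Background autofluorescence level in counts.
#' @param seed Integer seed; the same seed reproduces the scene exactly.
#' @return A `synthetic_scene` object.
#' @export
make_scene <- function(width = 480L, height = 360L, depth_range = c(85, 115),
                       texture_grain = 1.5, n_blobs = 6L,
                       patch_fraction = 0.04, patch_aspect = 1.6,
                       patch_level = 200, uv_background = 20, seed = 1L) {
  if (depth_range[1] >= depth_range[2])
    stop("depth_range must satisfy near < far")
  if (patch_fraction < 0 || patch_fraction >= 1)
    stop("patch_fraction must be in [0, 1)")
  with_seed(seed, {
    h <- as.integer(height); w <- as.integer(width)
    # leaf relief: mixture of Gaussian blobs, normalized to [0, 1]
    cu <- runif(n_blobs, 0.18 * w, 0.82 * w)
    cv <- runif(n_blobs, 0.18 * h, 0.82 * h)
    sd_blob <- runif(n_blobs, 0.10, 0.22) * min(h, w)
    uu <- matrix(0:(w - 1), h, w, byrow = TRUE)
    vv <- matrix(0:(h - 1), h, w)
    bump <- 0
    for (i in seq_len(n_blobs))
      bump <- bump + exp(-((uu - cu[i])^2 + (vv - cv[i])^2) / (2 * sd_blob[i]^2))
    bump <- norm01(cpp_gaussian_blur(bump, 2))
    leaf <- bump > 0.25
    depth <- depth_range[2] - bump * (depth_range[2] - depth_range[1])
    # reflectance: green-dominant speckle on the leaf, achromatic background
    sg <- smooth_noise(h, w, texture_grain)
    sr <- smooth_noise(h, w, texture_grain)
    sb <- smooth_noise(h, w, texture_grain)
    sbg <- smooth_noise(h, w, texture_grain)
    bg <- 0.30 + 0.10 * sbg
    refl <- list(
      red   = ifelse(leaf, 0.18 + 0.06 * sr, bg),
      green = ifelse(leaf, 0.50 + 0.22 * sg, bg),
      blue  = ifelse(leaf, 0.15 + 0.05 * sb, bg))
    illum <- 0.5 + 0.5 * norm01(cpp_gaussian_blur(matrix(rnorm(h * w), h, w), w / 6))
    ambient <- 0.28 * norm01(cpp_gaussian_blur(matrix(rnorm(h * w), h, w), w / 8))
    # fluorescence patch: the round(p * n_leaf) leaf pixels closest (in an
    # elliptical metric) to the tallest leaf point -- the count is exact
    patch <- matrix(FALSE, h, w)
    if (patch_fraction > 0) {
      k <- round(patch_fraction * sum(leaf))
      if (k > 0) {
        ctr <- which(bump == max(bump), arr.ind = TRUE)[1, ]
        li <- which(leaf, arr.ind = TRUE)
        du <- (li[, 2] - ctr[2]) / patch_aspect
        dv <- li[, 1] - ctr[1]
        ord <- order(du^2 + dv^2)
        patch[li[ord[seq_len(k)], , drop = FALSE]] <- TRUE
      }
    }
    uv_emission <- cpp_gaussian_blur(
      ifelse(patch, patch_level, uv_background), 0.5)
    structure(list(width = w, height = h, depth = depth, leaf_mask = leaf,
                   patch_mask = patch, reflectance = refl, illum = illum,
                   ambient = ambient, uv_emission = uv_emission, seed = seed,
                   params = list(depth_range = depth_range,
                                 texture_grain = texture_grain,
                                 patch_fraction = patch_fraction,
                                 patch_level = patch_level,
                                 uv_background = uv_background)),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene %dx%d: depth [%g, %g], %d leaf px, %d patch px, seed %d>\n",
    x$height, x$width, min(x$depth), max(x$depth), sum(x$leaf_mask),
    sum(x$patch_mask), x$seed))
  invisible(x)
}

#' Pinhole intrinsics matched to a synthetic scene
#'
#' Focal length in pixels is `1.25 * width` (a moderate field of view) and
#' the principal point sits at the frame centre.
#'
#' @param scene A `synthetic_scene`.
#' @param f Focal length in mm.
#' @param s Reprojection scale factor.
#' @export
synth_intrinsics <- function(scene, f = 8, s = 0.02) {
  fpx <- 1.25 * scene$width
  camera_intrinsics(f = f, ku = fpx / f, kv = fpx / f,
                    u0 = (scene$width - 1) / 2, v0 = (scene$height - 1) / 2,
                    s = s)
}

# Continuous (pre-noise) channel maps in counts for the reference view.
scene_channel_counts <- function(scene, maxc = 255) {
  lapply(scene$reflectance, function(r)
    maxc * pmin(pmax(scene$illum * r + scene$ambient, 0), 1))
}

quantize_frame <- function(m, noise_sd, maxc = 255) {
  if (noise_sd > 0) m <- m + rnorm(length(m), sd = noise_sd)
  intensity_image(matrix(pmin(pmax(round(m), 0), maxc), nrow(m), ncol(m)), 8L)
}

#' Render a rectified stereo pair of a synthetic scene
#'
#' The second camera is the first translated by `baseline` along +X (the
#' small-angle approximation of a turntable step about a vertical axis),
#' so the model matches the rectified-stereo geometry the Q matrix assumes:
#' every surface point obeys `d = f_px * baseline / Z` exactly.  Rendering
#' is a z-buffered per-row forward warp of the reference-view surface.
#' The UV fluorescence frame is attached to the first view.
#'
#' @param scene A `synthetic_scene`.
#' @param intr Camera intrinsics (default [synth_intrinsics()]).
#' @param baseline Camera translation in world units.
#' @param noise_sd Additive Gaussian sensor noise in counts (seeded).
#' @param seed Seed for the sensor noise (derived from the scene seed by
#'   default).
#' @return A list of two `rendered_view` objects `a` and `b`; each carries
#'   `$frames` (a [spectral_frames()]), `$true_depth`,
#'   `$true_disparity` (the per-pixel `f_px * baseline / Z`), `$fku` and
#'   `$baseline`.
#' @export
render_views <- function(scene, intr = synth_intrinsics(scene), baseline = 2,
                         noise_sd = 1, seed = scene$seed + 1000L) {
  if (baseline <= 0) stop("baseline must be positive")
  if (any(scene$depth <= 0)) stop("surface must lie in front of the camera")
  fku <- intr$f * intr$ku
  counts <- scene_channel_counts(scene)
  warp <- cpp_row_warp(counts, scene$depth, fku * baseline, 4L)
  with_seed(seed, {
    frames_a <- spectral_frames(
      red = quantize_frame(counts$red, noise_sd),
      green = quantize_frame(counts$green, noise_sd),
      blue = quantize_frame(counts$blue, noise_sd),
      uv_green = quantize_frame(scene$uv_emission, noise_sd),
      view_angle = 0)
    frames_b <- spectral_frames(
      red = quantize_frame(warp$textures[[1]], noise_sd),
      green = quantize_frame(warp$textures[[2]], noise_sd),
      blue = quantize_frame(warp$textures[[3]], noise_sd),
      view_angle = 0)
    view_a <- structure(list(frames = frames_a, true_depth = scene$depth,
                             true_disparity = fku * baseline / scene$depth,
                             fku = fku, baseline = baseline, offset = 0),
                        class = "rendered_view")
    view_b <- structure(list(frames = frames_b, true_depth = warp$depth,
                             true_disparity = fku * baseline / warp$depth,
                             fku = fku, baseline = baseline, offset = baseline),
                        class = "rendered_view")
    list(a = view_a, b = view_b)
  })
}

#' @export
print.rendered_view <- function(x, ...) {
  cat(sprintf("<rendered_view %dx%d, baseline offset %g>\n",
              nrow(x$frames$red), ncol(x$frames$red), x$offset))
  invisible(x)
}

#' Ground-truth correspondence of reference-view pixels in the second view
#'
#' For reference-view locations `(u, v)` of a stereo pair rendered by
#' [render_views()], returns where the same surface point appears in the
#' second view: `u' = u - f_px * baseline / Z(u, v)`, `v' = v`.
#'
#' @param view_a The reference `rendered_view`.
#' @param u,v Query locations (0-based pixels).
#' @export
true_correspondence <- function(view_a, u, v) {
  d <- cpp_interp_bicubic(view_a$true_disparity, u, v)
  data.frame(u = u - d, v = v)
}

#' Render a turntable sequence by true rotation
#'
#' Rotates the scene surface about a vertical axis placed on the optical
#' axis at distance `radius` (the rotation-stage axis) and re-renders each
#' requested angle with a z-buffered forward warp.  Unlike the rectified
#' stereo pair of [render_views()], appearance genuinely changes with angle
#' (foreshortening, occlusion), which is what the angle-step study
#' measures.
#'
#' @param scene A `synthetic_scene`.
#' @param intr Camera intrinsics.
#' @param angles Turntable angles in degrees (e.g. `0:4`).
#' @param radius Distance from the camera to the rotation axis; defaults to
#'   the mid depth of the scene.
#' @param noise_sd Additive sensor noise in counts.
#' @param seed Seed for the sensor noise.
#' @return A list of [spectral_frames()] objects, one per angle, with
#'   `view_angle` set.
#' @export
render_turntable_sequence <- function(scene, intr = synth_intrinsics(scene),
                                      angles = 0:4, radius = NULL,
                                      noise_sd = 1,
                                      seed = scene$seed + 2000L) {
  if (is.null(radius)) radius <- mean(scene$params$depth_range)
  fku <- intr$f * intr$ku
  fkv <- intr$f * intr$kv
  counts <- scene_channel_counts(scene)
  h <- scene$height; w <- scene$width
  uu <- matrix(0:(w - 1), h, w, byrow = TRUE)
  vv <- matrix(0:(h - 1), h, w)
  Z <- scene$depth
  X <- (uu - intr$u0) * Z / fku
  Y <- (intr$v0 - vv) * Z / fkv
  with_seed(seed, {
    lapply(angles, function(theta) {
      th <- theta * pi / 180
      dz <- Z - radius
      Xr <- cos(th) * X + sin(th) * dz
      Zr <- radius + (-sin(th) * X + cos(th) * dz)
      map_u <- fku * Xr / Zr + intr$u0
      map_v <- intr$v0 - fkv * Y / Zr
      warp <- cpp_forward_warp2d(counts, Zr, map_u, map_v, h, w, 2L)
      spectral_frames(red = quantize_frame(warp$textures[[1]], noise_sd),
                      green = quantize_frame(warp$textures[[2]], noise_sd),
                      blue = quantize_frame(warp$textures[[3]], noise_sd),
                      view_angle = theta %% 360)
    })
  })
}

#' Write a rendered scene to disk as a plain-image fixture set
#'
#' Writes the 6 structural frames (2 views x R/G/B) and the single UV
#' fluorescence frame as 8-bit PNGs named `{angle}_{channel}.png`, the
#' ground-truth depth and disparity of the reference view as 32-bit float
#' TIFFs, and a JSON sidecar with the scene parameters.  This is the
#' acquisition plan of the method: 7 camera images in total.
#'
#' @param views A stereo pair from [render_views()].
#' @param dir Output directory (created if needed).
#' @param labels Angle labels for the two views.
#' @return Invisibly, the paths written.
#' @export
write_scene_fixture <- function(views, dir, labels = c("000", "001")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(img, name) {
    p <- file.path(dir, name)
    png::writePNG(unclass(img) / 255, p)
    paths <<- c(paths, p)
  }
  for (i in 1:2) {
    v <- views[[i]]
    wr(v$frames$red, sprintf("%s_R.png", labels[i]))
    wr(v$frames$green, sprintf("%s_G.png", labels[i]))
    wr(v$frames$blue, sprintf("%s_B.png", labels[i]))
  }
  wr(views$a$frames$uv_green, sprintf("%s_UVG.png", labels[1]))
  dp <- file.path(dir, "true_depth.tif")
  di <- file.path(dir, "true_disparity.tif")
  tiff::writeTIFF(views$a$true_depth / max(views$a$true_depth), dp,
                  bits.per.sample = 32L)
  tiff::writeTIFF(views$a$true_disparity / max(views$a$true_disparity), di,
                  bits.per.sample = 32L)
  meta <- file.path(dir, "scene.json")
  jsonlite::write_json(list(baseline = views$a$baseline, fku = views$a$fku,
                            depth_scale = max(views$a$true_depth),
                            disparity_scale = max(views$a$true_disparity),
                            n_images = length(paths)),
                       meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, dp, di, meta))
}
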