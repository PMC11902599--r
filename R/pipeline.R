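# End-to-end orchestration: channel synthesis -> upsampling -> keypoints ->
# matching -> disparity -> reprojection -> densification -> disease overlay.

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

# Optional robust filter behind the `ransac` config flag: fits d ~ u + v by
# random sampling and keeps samples within `tol` pixels of the consensus
# plane.  Not applied by default.
ransac_disparity <- function(field, tol = 3, iters = 200, seed = 1L) {
  n <- nrow(field)
  if (n < 10) return(field)
  with_seed(seed, {
    A <- cbind(1, field$u, field$v)
    best <- rep(TRUE, n); nbest <- 0
    for (i in seq_len(iters)) {
      s <- sample.int(n, 3)
      M <- A[s, , drop = FALSE]
      if (abs(det(M)) < 1e-9) next
      beta <- solve(M, field$d[s])
      resid <- abs(A %*% beta - field$d)
      inl <- resid <= tol
      if (sum(inl) > nbest) { nbest <- sum(inl); best <- inl }
    }
    out <- field[best, , drop = FALSE]
    attributes(out)[c("n_dropped_zero", "n_dropped_drift", "image_shape",
                      "reference")] <-
      attributes(field)[c("n_dropped_zero", "n_dropped_drift", "image_shape",
                          "reference")]
    class(out) <- class(field)
    out
  })
}

# Matched-keypoint count for one channel of a view pair under a config;
# the shared core of reconstruct() and the study runners.
match_pair <- function(view_a, view_b, config, channel = NULL,
                       verbose = FALSE) {
  channel <- if (is.null(channel)) config$channel_for_matching else channel
  cha <- get_channel(view_a, channel)
  chb <- get_channel(view_b, channel)
  img_a <- upsample(normalize_for_detection(cha), config$upsample_factor)
  img_b <- upsample(normalize_for_detection(chb), config$upsample_factor)
  kpa <- detect_keypoints(img_a, config$nfeatures, config$double_image)
  kpb <- detect_keypoints(img_b, config$nfeatures, config$double_image)
  log_stage(verbose, "keypoints: %d (view a), %d (view b) on %s channel",
            nrow(kpa$pts), nrow(kpb$pts), channel)
  matches <- match_keypoints(kpa, kpb, ratio = config$match_ratio,
                             method = config$match_method,
                             trees = config$ann$trees,
                             checks = config$ann$checks, seed = config$seed)
  log_stage(verbose, "matches kept by ratio test (<= %g): %d",
            config$match_ratio, nrow(matches))
  list(channel = cha, kpa = kpa, kpb = kpb, matches = matches)
}

#' Reconstruct a 3D plant point cloud from a two-view pair
#'
#' Runs the full pipeline in order: the matching channel (ExG by default)
#' is computed for both views, normalized, digitally upsampled, SIFT
#' keypoints are detected and matched with the ratio test, per-match
#' horizontal disparities are extracted and filtered, samples are
#' reprojected through the Q matrix to world coordinates, the sparse cloud
#' is densified over the plant mask, and - when the first view carries a UV
#' fluorescence frame - the thresholded disease mask is registered onto the
#' cloud and summarised as a coverage statistic.
#'
#' @param view_a,view_b [spectral_frames()] bundles of the two views;
#'   `view_a` is the reference and may carry the UV frame.
#' @param config A [recon_config()].
#' @param verbose Log per-stage counts.
#' @return A `plant_recon` object: `$cloud` (dense unless
#'   `config$densify` is off), `$sparse`, `$report` (a `disease_report` or
#'   `NULL`), `$matches` (matched pixel pairs in native units), `$counts`,
#'   `$Q`, `$config`.
#' @export
reconstruct <- function(view_a, view_b, config = recon_config(),
                        verbose = TRUE) {
  check_frames(view_a); check_frames(view_b)
  mp <- match_pair(view_a, view_b, config, verbose = verbose)
  if (nrow(mp$matches) == 0)
    stop("no keypoint matches between the two views; cannot reconstruct")
  field_up <- compute_disparity(mp$matches, mp$kpa, mp$kpb,
                                config$max_vertical_drift * config$upsample_factor)
  if (nrow(field_up) == 0)
    stop("all matched keypoints have zero disparity or excessive vertical ",
         "drift (are the two views identical?)")
  if (isTRUE(config$ransac))
    field_up <- ransac_disparity(field_up, config$ransac_tol,
                                 seed = config$seed)
  field <- rescale_disparity(field_up, config$upsample_factor)
  log_stage(verbose,
            "disparities retained: %d (dropped %d zero, %d drifted)",
            nrow(field), attr(field, "n_dropped_zero"),
            attr(field, "n_dropped_drift"))
  Q <- build_Q(as_intrinsics(config))
  exg <- if (identical(attr(mp$channel, "channel_kind"), "exg")) mp$channel
         else compute_exg(view_a)
  sparse <- reproject_field(field, Q, exg, config$world_scale)
  cloud <- sparse
  if (isTRUE(config$densify)) {
    mask <- plant_mask(exg, config$mask_min_exg, config$mask_smooth_sigma)
    cloud <- densify(sparse, mask, config$densify_method, exg)
    log_stage(verbose, "densified to %d points over %d masked pixels",
              nrow(cloud), sum(mask))
  }
  report <- NULL
  if (!is.null(view_a$uv_green)) {
    dm <- threshold_disease(view_a$uv_green, config$disease_threshold)
    cloud <- register_disease(cloud, dm)
    sparse <- register_disease(sparse, dm)
    report <- disease_coverage(cloud, config$disease_threshold)
    log_stage(verbose, "disease: %d of %d points flagged (%.2f%%)",
              report$n_disease_pixels, report$n_structure_points,
              100 * report$coverage_fraction)
  } else {
    warning("no UV fluorescence frame in view_a: structural-only output")
  }
  f <- config$upsample_factor
  matches_df <- data.frame(
    u_a = mp$kpa$pts$u[mp$matches$index_a] / f,
    v_a = mp$kpa$pts$v[mp$matches$index_a] / f,
    u_b = mp$kpb$pts$u[mp$matches$index_b] / f,
    v_b = mp$kpb$pts$v[mp$matches$index_b] / f)
  matches_df$d <- abs(matches_df$u_b - matches_df$u_a)
  structure(list(cloud = cloud, sparse = sparse, report = report,
                 matches = matches_df,
                 counts = list(keypoints_a = nrow(mp$kpa$pts),
                               keypoints_b = nrow(mp$kpb$pts),
                               matches = nrow(mp$matches),
                               disparities = nrow(field),
                               dense_points = nrow(cloud)),
                 Q = Q, config = config),
            class = "plant_recon")
}

#' @export
print.plant_recon <- function(x, ...) {
  cat("Turntable structure-from-motion reconstruction\n")
  cat(sprintf("  keypoints: %d / %d   matches: %d   disparities: %d\n",
              x$counts$keypoints_a, x$counts$keypoints_b, x$counts$matches,
              x$counts$disparities))
  cat(sprintf("  cloud: %d points\n", nrow(x$cloud)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' @export
summary.plant_recon <- function(object, ...) {
  cl <- object$cloud
  out <- list(counts = object$counts,
              depth_range = if (nrow(cl)) range(cl$Z) else c(NA, NA),
              coverage = if (is.null(object$report)) NA_real_ else
                object$report$coverage_fraction)
  class(out) <- "summary.plant_recon"
  out
}

#' @export
print.summary.plant_recon <- function(x, ...) {
  cat(sprintf("points %d, matches %d, Z in [%.4g, %.4g], coverage %s\n",
              x$counts$dense_points, x$counts$matches, x$depth_range[1],
              x$depth_range[2],
              if (is.na(x$coverage)) "n/a" else sprintf("%.2f%%",
                                                        100 * x$coverage)))
  invisible(x)
}

#' Plot a reconstructed cloud as a depth-coded image-plane projection
#'
#' Points are drawn at their source pixels, coloured near-to-far; disease
#' points are overdrawn in red.
#'
#' @param x A `plant_recon`.
#' @param max_points Subsample cap for plotting speed.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.plant_recon <- function(x, max_points = 50000L, ...) {
  cl <- x$cloud
  if (nrow(cl) > max_points)
    cl <- cl[round(seq(1, nrow(cl), length.out = max_points)), ]
  pal <- hcl.colors(64, "viridis")
  zi <- cut(cl$Z, 64, labels = FALSE)
  plot(cl$u, -cl$v, pch = ".", col = pal[zi], asp = 1,
       xlab = "u (px)", ylab = "-v (px)", ...)
  if (any(cl$disease)) points(cl$u[cl$disease], -cl$v[cl$disease],
                              pch = ".", col = "red")
  title(main = sprintf("%d points (depth-coded%s)", nrow(x$cloud),
                       if (any(cl$disease)) ", disease in red" else ""))
  invisible(x)
}
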