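# Keypoint detection (SIFT), descriptor matching with the Lowe ratio test,
# and disparity extraction for a two-view pair.

#' Detect SIFT keypoints
#'
#' Scale-space difference-of-Gaussian extrema with gradient-histogram
#' descriptors (the standard SIFT formulation: quadratic subpixel
#' refinement, contrast and edge-response rejection, 36-bin orientation
#' assignment, 4x4x8 descriptor).  Deterministic: the same image always
#' yields the same keypoint list.
#'
#' @param image An 8-bit [intensity_image()].
#' @param nfeatures Keep only the `nfeatures` strongest keypoints
#'   (0 = keep all).
#' @param double_image Double the image before building the pyramid
#'   (recovers the finest-scale features; costs 4x memory).
#' @return A `sift_keypoints` object: `$pts` is a data frame with 0-based
#'   pixel coordinates `u`, `v` plus `diameter`, `angle`, `response`,
#'   `octave`; `$desc` is the matching 128-column descriptor matrix.
#' @export
detect_keypoints <- function(image, nfeatures = 0L, double_image = TRUE) {
  if (bit_depth_of(image) != 8L)
    stop("keypoint detection expects an 8-bit image; see normalize_for_detection()")
  m <- unclass(image) / 255
  res <- if (min(dim(m)) < 16) {
    list(pts = matrix(numeric(0), 0, 6,
                      dimnames = list(NULL, c("u", "v", "diameter", "angle",
                                              "response", "octave"))),
         desc = matrix(numeric(0), 0, 128))
  } else {
    cpp_sift(m, as.integer(nfeatures), isTRUE(double_image))
  }
  structure(list(pts = as.data.frame(res$pts), desc = res$desc,
                 image_shape = dim(m)),
            class = "sift_keypoints")
}

#' @export
print.sift_keypoints <- function(x, ...) {
  cat(sprintf("<sift_keypoints: %d keypoints on a %dx%d image>\n",
              nrow(x$pts), x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

empty_match_set <- function(shape) {
  structure(data.frame(index_a = integer(0), index_b = integer(0),
                       best_distance = numeric(0), second_distance = numeric(0)),
            image_shape = shape, class = c("match_set", "data.frame"))
}

#' Match keypoints between two views with a ratio test
#'
#' For every keypoint of `set_a` the two nearest neighbours in `set_b` by
#' Euclidean descriptor distance are found, and the pair is kept iff
#' `best_distance / second_distance <= ratio` (comparison is `<=` at the
#' boundary).  The default search uses randomized kd-trees (an approximate
#' nearest-neighbour index in the FLANN style, 5 trees); `method = "exact"`
#' is the exhaustive brute-force search and serves as the oracle for the
#' approximate mode.  With `checks >= nrow` of the candidate set the
#' kd-tree search is itself exhaustive and exact.
#'
#' @param set_a,set_b `sift_keypoints` objects with equal descriptor length.
#' @param ratio Lowe distance-ratio cutoff (default 0.6).
#' @param method `"kdtree"` (approximate, default) or `"exact"`.
#' @param trees Number of randomized kd-trees (default 5).
#' @param checks Leaf-check budget per query for the approximate search.
#' @param seed Seed for the randomized tree construction.
#' @return A `match_set` data frame: `index_a`, `index_b`, `best_distance`,
#'   `second_distance`; one row per kept pair, each `index_a` at most once.
#' @export
match_keypoints <- function(set_a, set_b, ratio = 0.6,
                            method = c("kdtree", "exact"), trees = 5L,
                            checks = 128L, seed = 1234L) {
  method <- match.arg(method)
  if (ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1]")
  na <- nrow(set_a$desc); nb <- nrow(set_b$desc)
  if (na == 0 || nb < 2) return(empty_match_set(set_a$image_shape))
  if (ncol(set_a$desc) != ncol(set_b$desc))
    stop("descriptor lengths differ between the two keypoint sets")
  nn <- if (method == "exact") {
    cpp_match_bruteforce(set_a$desc, set_b$desc)
  } else {
    cpp_match_kdtree(set_a$desc, set_b$desc, as.integer(trees),
                     as.integer(checks), as.integer(seed))
  }
  keep <- nn$d1 <= ratio * nn$d2
  structure(data.frame(index_a = seq_len(na)[keep], index_b = nn$idx[keep],
                       best_distance = nn$d1[keep],
                       second_distance = nn$d2[keep]),
            image_shape = set_a$image_shape,
            class = c("match_set", "data.frame"))
}

#' Extract per-point disparities from matched keypoints
#'
#' The disparity of a matched pair is the horizontal displacement magnitude
#' `d = |u_b - u_a|`: the turntable rotates about a vertical axis, so the
#' dominant apparent motion between consecutive views is horizontal.  Each
#' retained sample is anchored at the reference-view location `(u_a, v_a)`.
#' Pairs with zero disparity, or whose vertical drift `|v_b - v_a|` exceeds
#' `max_vertical_drift` (gross mismatches), are discarded and counted.
#'
#' @param matches A `match_set` from [match_keypoints()].
#' @param kps_a,kps_b The keypoint sets the matches index into.
#' @param max_vertical_drift Maximum allowed `|v_b - v_a|` in pixels.
#' @return A `disparity_field` data frame (`u`, `v`, `d`) with attributes
#'   `n_dropped_zero` and `n_dropped_drift`.
#' @export
compute_disparity <- function(matches, kps_a, kps_b, max_vertical_drift = 20) {
  if (nrow(matches) == 0) {
    warning("empty match set: returning an empty disparity field")
    return(structure(data.frame(u = numeric(0), v = numeric(0), d = numeric(0)),
                     n_dropped_zero = 0L, n_dropped_drift = 0L,
                     image_shape = attr(matches, "image_shape"),
                     reference = "a", class = c("disparity_field", "data.frame")))
  }
  ua <- kps_a$pts$u[matches$index_a]; va <- kps_a$pts$v[matches$index_a]
  ub <- kps_b$pts$u[matches$index_b]; vb <- kps_b$pts$v[matches$index_b]
  d <- abs(ub - ua)
  drift <- abs(vb - va)
  zero <- d == 0
  drifted <- !zero & drift > max_vertical_drift
  keep <- !zero & !drifted
  structure(data.frame(u = ua[keep], v = va[keep], d = d[keep]),
            n_dropped_zero = sum(zero), n_dropped_drift = sum(drifted),
            image_shape = attr(matches, "image_shape"),
            reference = "a", class = c("disparity_field", "data.frame"))
}

#' Rescale a disparity field measured on upsampled images to native pixels
#'
#' Keypoints found on a `factor`-times upsampled frame have coordinates and
#' disparities in upsampled pixel units; the camera model works in native
#' pixels, so everything is divided by `factor` before reprojection.
#'
#' @param field A `disparity_field`.
#' @param factor The upsampling factor the images were enlarged by.
#' @export
rescale_disparity <- function(field, factor) {
  if (factor == 1) return(field)
  out <- field
  out$u <- field$u / factor
  out$v <- field$v / factor
  out$d <- field$d / factor
  shp <- attr(field, "image_shape")
  if (!is.null(shp)) attr(out, "image_shape") <- as.integer(round(shp / factor))
  out
}

#' Dump matched keypoint pairs to a TSV file for inspection
#'
#' @param matches A `match_set`.
#' @param kps_a,kps_b The keypoint sets the matches index into.
#' @param path Output file.
#' @export
write_matches_tsv <- function(matches, kps_a, kps_b, path) {
  df <- data.frame(u_a = kps_a$pts$u[matches$index_a],
                   v_a = kps_a$pts$v[matches$index_a],
                   u_b = kps_b$pts$u[matches$index_b],
                   v_b = kps_b$pts$v[matches$index_b])
  df$d <- abs(df$u_b - df$u_a)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
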