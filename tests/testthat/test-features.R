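blob_image <- function(centers, size = 200L, sigma = 3, amp = 150, bg = 30) {
  m <- matrix(bg, size, size)
  uu <- matrix(0:(size - 1), size, size, byrow = TRUE)
  vv <- matrix(0:(size - 1), size, size)
  for (k in seq_len(nrow(centers)))
    m <- m + amp * exp(-((uu - centers[k, 1])^2 + (vv - centers[k, 2])^2) /
                         (2 * sigma^2))
  intensity_image(round(pmin(m, 255)))
}

test_that("keypoint detection finds isolated blobs near their centres", {
  centers <- as.matrix(expand.grid(u = c(40, 80, 120, 160, 100),
                                   v = c(50, 150)))[1:10, ]
  img <- blob_image(centers)
  kp <- detect_keypoints(img)
  expect_gte(nrow(kp$pts), 10)
  for (k in 1:10) {
    dmin <- min(sqrt((kp$pts$u - centers[k, 1])^2 +
                     (kp$pts$v - centers[k, 2])^2))
    expect_lt(dmin, 3)
  }
})

test_that("keypoint detection is deterministic and empty on flat images", {
  expect_equal(nrow(detect_keypoints(intensity_image(matrix(128, 64, 64)))$pts), 0)
  centers <- cbind(c(30, 70, 50), c(30, 30, 70))
  img <- blob_image(centers, size = 100L)
  a <- detect_keypoints(img)
  b <- detect_keypoints(img)
  expect_identical(a$pts, b$pts)
  expect_identical(a$desc, b$desc)
})

test_that("the ratio test keeps best/second <= ratio and rejects above it", {
  # three 128-d descriptors at known distances from a query at the origin
  d_at <- function(r) c(r, rep(0, 127))
  a <- make_kps(0, 0, desc = rbind(rep(0, 128)))
  b_keep <- make_kps(c(0, 0), c(0, 0), desc = rbind(d_at(0.5), d_at(1.0)))
  b_drop <- make_kps(c(0, 0), c(0, 0), desc = rbind(d_at(0.9), d_at(1.0)))
  m1 <- match_keypoints(a, b_keep, ratio = 0.6, method = "exact")
  expect_equal(nrow(m1), 1)
  expect_equal(m1$best_distance, 0.5)
  expect_equal(m1$second_distance, 1.0)
  m2 <- match_keypoints(a, b_drop, ratio = 0.6, method = "exact")
  expect_equal(nrow(m2), 0)
  # boundary is kept: 0.6 / 1.0 at ratio 0.6
  b_edge <- make_kps(c(0, 0), c(0, 0), desc = rbind(d_at(0.6), d_at(1.0)))
  expect_equal(nrow(match_keypoints(a, b_edge, ratio = 0.6, method = "exact")), 1)
})

test_that("fewer than two candidates gives an empty match set", {
  a <- make_kps(0, 0, desc = matrix(rnorm(128), 1))
  b <- make_kps(0, 0, desc = matrix(rnorm(128), 1))
  expect_equal(nrow(match_keypoints(a, b)), 0)
})

test_that("approximate kd-tree matching equals exhaustive search on small sets", {
  set.seed(123)
  mk <- function(n) {
    d <- matrix(rnorm(n * 128), n)
    d <- d / sqrt(rowSums(d^2))
    make_kps(runif(n, 0, 500), runif(n, 0, 500), desc = d)
  }
  for (n in c(50, 100)) {
    a <- mk(n); b <- mk(n)
    ex <- match_keypoints(a, b, ratio = 1, method = "exact")
    ap <- match_keypoints(a, b, ratio = 1, method = "kdtree")
    expect_equal(ap$index_b, ex$index_b)
    expect_equal(ap$best_distance, ex$best_distance, tolerance = 1e-12)
    expect_equal(ap$second_distance, ex$second_distance, tolerance = 1e-12)
  }
})

test_that("lowering the ratio never increases the number of kept matches", {
  set.seed(321)
  a <- make_kps(runif(80), runif(80), desc = matrix(rnorm(80 * 128), 80))
  b <- make_kps(runif(120), runif(120), desc = matrix(rnorm(120 * 128), 120))
  counts <- vapply(seq(1.0, 0.2, by = -0.1), function(r)
    nrow(match_keypoints(a, b, ratio = r, method = "exact")), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("second-nearest distances agree with an exhaustive R oracle", {
  # matching a set against itself: best is the point itself (distance 0),
  # second is its true nearest neighbour with self excluded
  set.seed(11)
  d <- matrix(rnorm(40 * 128), 40)
  a <- make_kps(runif(40), runif(40), desc = d)
  m <- match_keypoints(a, a, ratio = 1, method = "exact")
  expect_equal(m$index_b, seq_len(40))
  expect_lt(max(m$best_distance), 1e-5)   # self-distance, up to BLAS roundoff
  D <- as.matrix(dist(d))
  diag(D) <- Inf
  expect_equal(m$second_distance, unname(apply(D, 1, min)), tolerance = 1e-6)
})

test_that("disparity extraction takes |u_b - u_a| and filters degeneracies", {
  kpa <- make_kps(c(100, 100, 50), c(50, 50, 10))
  kpb <- make_kps(c(110, 100, 60), c(50, 50, 80))
  matches <- structure(data.frame(index_a = 1:3, index_b = 1:3,
                                  best_distance = 0, second_distance = 1),
                       image_shape = c(1000L, 1000L),
                       class = c("match_set", "data.frame"))
  f <- compute_disparity(matches, kpa, kpb, max_vertical_drift = 20)
  expect_equal(nrow(f), 1)                       # zero-d and drifted dropped
  expect_equal(f$u, 100); expect_equal(f$v, 50); expect_equal(f$d, 10)
  expect_equal(attr(f, "n_dropped_zero"), 1L)
  expect_equal(attr(f, "n_dropped_drift"), 1L)
})

test_that("a frontoparallel plane yields the closed-form constant disparity", {
  sc <- scene_with_depth(matrix(100, 240, 320), seed = 13L)
  vs <- render_views(sc, baseline = 2, noise_sd = 0)
  fku <- vs$a$fku
  expect_equal(max(abs(vs$a$true_disparity - fku * 2 / 100)), 0)
  cfg <- synth_config(sc)
  mpts <- suppressMessages(
    reconstruct(vs$a$frames, vs$b$frames, cfg, verbose = FALSE))$matches
  expect_gt(nrow(mpts), 50)
  expect_true(mean(abs(mpts$d - fku * 2 / 100) <= 0.5) >= 0.9)
})
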