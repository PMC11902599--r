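test_that("Q has the exact perspective-matrix structure", {
  intr <- default_intrinsics()                    # f=8mm, 3.45um pixels
  Q <- build_Q(intr)
  expect_equal(Q[1, ], c(1, 0, 0, -720))
  expect_equal(Q[2, ], c(0, -1, 0, 540))
  expect_equal(Q[3, 3], 46.3768, tolerance = 1e-4)  # s*f*ku = 0.02*8/0.00345
  expect_equal(Q[3, c(1, 2, 4)], c(0, 0, 0))
  expect_equal(Q[4, ], c(0, 0, 0, 1))
  # linear in s
  intr2 <- camera_intrinsics(8, 1 / 0.00345, u0 = 720, v0 = 540, s = 0.04)
  expect_equal(build_Q(intr2)[3, 3], 2 * Q[3, 3])
  expect_error(camera_intrinsics(-1, 100, u0 = 0, v0 = 0), "positive")
})

test_that("reprojection matches the closed form for random inputs", {
  intr <- camera_intrinsics(8, 1 / 0.00345, u0 = 720, v0 = 540, s = 0.02)
  Q <- build_Q(intr)
  # principal ray maps to the optical axis
  p0 <- reproject_point(720, 540, 5, Q)
  expect_equal(c(p0$X, p0$Y), c(0, 0))
  expect_equal(p0$Z, 0.02 * 8 * (1 / 0.00345) / 5)
  # worked example with s*f*ku = 46.376
  Qx <- build_Q(camera_intrinsics(8, 46.376 / (0.02 * 8), u0 = 720, v0 = 540))
  px <- reproject_point(820, 440, 10, Qx)
  expect_equal(c(px$X, px$Y, px$Z), c(100, 100, 4.6376), tolerance = 1e-12)
  # closed-form oracle: X = u - u0, Y = v0 - v, Z = s*f*ku/d
  set.seed(99)
  u <- runif(1e4, 0, 1440); v <- runif(1e4, 0, 1080); d <- runif(1e4, 0.1, 300)
  got <- reproject_point(u, v, d, Q)
  sfku <- 0.02 * 8 / 0.00345
  expect_equal(got$X, u - 720, tolerance = 1e-12)
  expect_equal(got$Y, 540 - v, tolerance = 1e-12)
  expect_equal(got$Z, sfku / d, tolerance = 1e-12)
  expect_error(reproject_point(1, 1, 0, Q), "positive")
})

test_that("depth is strictly decreasing in disparity", {
  Q <- build_Q(default_intrinsics())
  d <- seq(0.5, 200, length.out = 400)
  Z <- reproject_point(rep(0, 400), rep(0, 400), d, Q)$Z
  expect_true(all(diff(Z) < 0))
})

test_that("field reprojection equals per-sample reprojection with sampled intensity", {
  intr <- camera_intrinsics(8, 300, u0 = 50, v0 = 40, s = 0.02)
  Q <- build_Q(intr)
  set.seed(5)
  field <- structure(data.frame(u = runif(100, 0, 99), v = runif(100, 0, 79),
                                d = runif(100, 1, 30)),
                     class = c("disparity_field", "data.frame"))
  inten <- channel_image(matrix(rnorm(80 * 100, sd = 50), 80, 100), "exg")
  cloud <- reproject_field(field, Q, inten)
  for (i in c(1, 17, 100)) {
    p <- reproject_point(field$u[i], field$v[i], field$d[i], Q)
    expect_equal(c(cloud$X[i], cloud$Y[i], cloud$Z[i]), c(p$X, p$Y, p$Z))
    expect_equal(cloud$intensity[i],
                 unclass(inten)[round(field$v[i]) + 1, round(field$u[i]) + 1])
  }
  expect_true(all(!cloud$disease))
  # constant disparity puts every point at one depth
  fc <- structure(data.frame(u = runif(20, 0, 99), v = runif(20, 0, 79),
                             d = 10),
                  class = c("disparity_field", "data.frame"))
  expect_equal(length(unique(reproject_field(fc, Q, inten)$Z)), 1)
})

test_that("densification interpolates linearly and fills the mask exactly", {
  intr <- camera_intrinsics(8, 300, u0 = 40, v0 = 30, s = 0.02)
  Q <- build_Q(intr)
  h <- 60L; w <- 80L
  set.seed(6)
  u <- c(0, w - 1, 0, w - 1, runif(40, 1, w - 2))
  v <- c(0, 0, h - 1, h - 1, runif(40, 1, h - 2))
  plane <- function(u, v) 2 + 0.01 * u + 0.02 * v
  cloud <- fluorosfm:::new_plant_cloud(
    data.frame(X = u - 40, Y = 30 - v, Z = plane(u, v),
               intensity = 0, disease = FALSE, u = u, v = v),
    Q, c(h, w), 1)
  mask <- matrix(TRUE, h, w)
  dense <- densify(cloud, mask, "linear")
  expect_equal(nrow(dense), h * w)       # one point per masked pixel
  expect_equal(dense$Z, plane(dense$u, dense$v), tolerance = 1e-6)
  # constant-depth samples give a constant dense field (both methods)
  cloud$Z <- rep(5, length(u))
  for (m in c("linear", "nearest")) {
    dn <- densify(cloud, mask, m)
    expect_true(all(abs(dn$Z - 5) < 1e-9))
  }
  # partial mask: count contract
  mask2 <- matrix(FALSE, h, w); mask2[10:20, 30:50] <- TRUE
  expect_equal(nrow(densify(cloud, mask2, "linear")), sum(mask2))
  # fewer than 3 samples falls back to nearest with a warning
  small <- cloud[1:2, ]
  attributes(small)[c("q_matrix", "image_shape", "world_scale")] <-
    attributes(cloud)[c("q_matrix", "image_shape", "world_scale")]
  class(small) <- class(cloud)
  expect_warning(densify(small, mask2, "linear"), "nearest")
})

test_that("PLY output round-trips through an ASCII parse", {
  Q <- build_Q(camera_intrinsics(8, 300, u0 = 10, v0 = 10))
  cloud <- fluorosfm:::new_plant_cloud(
    data.frame(X = c(1.5, -2), Y = c(0, 3.25), Z = c(4, 5),
               intensity = c(10, -7.5), disease = c(TRUE, FALSE),
               u = c(0, 1), v = c(0, 1)),
    Q, c(2L, 2L), 1)
  path <- tempfile(fileext = ".ply")
  write_ply(cloud, path)
  lines <- readLines(path)
  expect_equal(lines[1], "ply")
  expect_equal(lines[2], "format ascii 1.0")
  nv <- as.integer(sub("element vertex ", "",
                       grep("element vertex", lines, value = TRUE)))
  expect_equal(nv, 2L)
  body <- read.table(text = lines[(which(lines == "end_header") + 1):length(lines)])
  expect_equal(body$V1, cloud$X)
  expect_equal(body$V4, cloud$intensity)
  expect_equal(body$V5, as.integer(cloud$disease))
  # binary variant writes 17-byte records (4 floats + 1 uchar) after the header
  pb <- tempfile(fileext = ".ply")
  write_ply(cloud, pb, binary = TRUE)
  raw <- readBin(pb, "raw", file.size(pb))
  data_start <- grepRaw("end_header\n", raw, fixed = TRUE) + nchar("end_header\n")
  expect_equal(length(raw) - data_start + 1, 2L * 17L)
  x1 <- readBin(raw[data_start + 0:3], "numeric", 1, size = 4, endian = "little")
  expect_equal(x1, 1.5, tolerance = 1e-7)
})
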