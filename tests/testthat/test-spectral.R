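test_that("grayscale is the unweighted per-pixel mean of R, G and B", {
  fr <- spectral_frames(red = intensity_image(matrix(30, 2, 2)),
                        green = intensity_image(matrix(60, 2, 2)),
                        blue = intensity_image(matrix(90, 2, 2)))
  expect_equal(unclass(to_gray(fr))[1, 1], 60)

  cc <- intensity_image(matrix(123, 3, 4))
  expect_equal(unclass(to_gray(spectral_frames(cc, cc, cc))),
               matrix(123, 3, 4), ignore_attr = TRUE)

  # scalar-loop oracle on random 8-bit 16x16 frames
  set.seed(42)
  r <- matrix(sample(0:255, 256, TRUE), 16)
  g <- matrix(sample(0:255, 256, TRUE), 16)
  b <- matrix(sample(0:255, 256, TRUE), 16)
  fr <- spectral_frames(intensity_image(r), intensity_image(g),
                        intensity_image(b))
  oracle <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) oracle[i, j] <- (r[i, j] + g[i, j] + b[i, j]) / 3
  expect_equal(unclass(to_gray(fr)), oracle, ignore_attr = TRUE)
})

test_that("ExG is 2G - R - B, signed and unclipped", {
  mk <- function(r, g, b)
    spectral_frames(intensity_image(matrix(r, 1, 1)),
                    intensity_image(matrix(g, 1, 1)),
                    intensity_image(matrix(b, 1, 1)))
  expect_equal(as.numeric(compute_exg(mk(10, 20, 5))), 25)
  expect_equal(as.numeric(compute_exg(mk(200, 200, 200))), 0)
  expect_equal(as.numeric(compute_exg(mk(255, 0, 255))), -510)
})

test_that("ExG is homogeneous of degree one in the channel intensities", {
  set.seed(7)
  r <- matrix(sample(0:60, 64, TRUE), 8)
  g <- matrix(sample(0:60, 64, TRUE), 8)
  b <- matrix(sample(0:60, 64, TRUE), 8)
  base <- compute_exg(spectral_frames(intensity_image(r), intensity_image(g),
                                      intensity_image(b)))
  for (a in c(2L, 4L)) {
    scaled <- compute_exg(spectral_frames(intensity_image(a * r),
                                          intensity_image(a * g),
                                          intensity_image(a * b)))
    expect_equal(unclass(scaled), a * unclass(base), ignore_attr = TRUE)
  }
})

test_that("channel synthesis commutes with cropping", {
  set.seed(8)
  r <- matrix(sample(0:255, 400, TRUE), 20)
  g <- matrix(sample(0:255, 400, TRUE), 20)
  b <- matrix(sample(0:255, 400, TRUE), 20)
  fr <- spectral_frames(intensity_image(r), intensity_image(g),
                        intensity_image(b))
  crop <- function(m) m[3:12, 5:18]
  fr_c <- spectral_frames(intensity_image(crop(r)), intensity_image(crop(g)),
                          intensity_image(crop(b)))
  expect_equal(unclass(compute_exg(fr_c)), crop(unclass(compute_exg(fr))),
               ignore_attr = TRUE)
  expect_equal(unclass(to_gray(fr_c)), crop(unclass(to_gray(fr))),
               ignore_attr = TRUE)
})

test_that("frame sets reject mismatched shapes", {
  expect_error(spectral_frames(intensity_image(matrix(0, 2, 2)),
                               intensity_image(matrix(0, 2, 3)),
                               intensity_image(matrix(0, 2, 2))),
               "dimensions")
})

test_that("detector normalization is an affine min-max map to [0, 255]", {
  m <- channel_image(matrix(c(-50, 150, 50, 0), 2, 2), "exg")
  out <- normalize_for_detection(m)
  expect_equal(attr(out, "bit_depth"), 8L)
  expect_equal(unclass(out)[1, 1], 0)     # min -> 0
  expect_equal(unclass(out)[2, 1], 255)   # max -> 255
  expect_equal(unclass(out)[1, 2], 128)   # round(255 * 100 / 200)

  const <- channel_image(matrix(7, 3, 3), "gray")
  expect_true(all(unclass(normalize_for_detection(const)) == 0))

  # non-constant input always spans the full range
  set.seed(9)
  for (i in 1:5) {
    x <- channel_image(matrix(rnorm(100, sd = 40), 10), "exg")
    y <- unclass(normalize_for_detection(x))
    expect_equal(range(y), c(0, 255))
  }
})

test_that("bicubic upsampling multiplies dimensions and preserves identities", {
  set.seed(10)
  img <- intensity_image(matrix(sample(0:255, 30 * 40, TRUE), 30, 40))
  up <- upsample(img, 3L)
  expect_equal(dim(up), c(90L, 120L))
  expect_equal(unclass(upsample(img, 1L)), unclass(img))
  cst <- intensity_image(matrix(77, 12, 9))
  expect_true(all(unclass(upsample(cst, 4L)) == 77))
  expect_error(upsample(img, 0), "factor")
})

test_that("upsampling reproduces source values at the original grid nodes", {
  # at factor f, source node y lands at output index f*y + (f-1)/2
  ramp <- intensity_image(outer(0:19, 0:19, function(i, j) i * 5 + j * 3))
  for (f in c(3L, 5L)) {
    up <- unclass(upsample(ramp, f))
    nodes_r <- f * (0:19) + (f - 1) %/% 2 + 1
    sub <- up[nodes_r, nodes_r]
    expect_true(max(abs(sub - unclass(ramp))) <= 1)
  }
})
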