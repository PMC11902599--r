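test_that("disease thresholding removes signals below tau and keeps the boundary", {
  img <- intensity_image(matrix(c(0, 109, 110, 200), 2, 2))
  m <- threshold_disease(img, tau = 110)
  expect_equal(as.vector(unclass(m)), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(attr(m, "positive_count"), 2L)

  z <- threshold_disease(intensity_image(matrix(0, 5, 5)))
  expect_equal(attr(z, "positive_count"), 0L)
  expect_false(any(z))

  # a constructed count is recovered exactly
  set.seed(2)
  mm <- matrix(0, 30, 30)
  mm[sample(900, 57)] <- 200
  expect_equal(attr(threshold_disease(intensity_image(mm), 110),
                    "positive_count"), 57L)
})

test_that("positive count is non-increasing in the threshold", {
  set.seed(3)
  img <- intensity_image(matrix(sample(0:255, 400, TRUE), 20))
  counts <- vapply(seq(0, 260, by = 20), function(tau)
    attr(threshold_disease(img, tau), "positive_count"), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("registration flags points by source pixel and changes nothing else", {
  fx <- small_fixture()
  cloud <- fx$rec$cloud
  all_false <- register_disease(cloud, threshold_disease(
    intensity_image(matrix(0, 300, 400)), 110))
  expect_false(any(all_false$disease))
  all_true <- register_disease(cloud, threshold_disease(
    intensity_image(matrix(255, 300, 400)), 110))
  expect_true(all(all_true$disease))
  # coordinates and intensities are untouched
  expect_equal(all_true[c("X", "Y", "Z", "intensity", "u", "v")],
               cloud[c("X", "Y", "Z", "intensity", "u", "v")])
  # flagged points are exactly those whose source pixel is in the patch
  patch <- fx$sc$patch_mask
  reg <- register_disease(cloud, structure(patch, class = c("disease_mask",
                                                            "matrix", "array")))
  expect_equal(reg$disease,
               patch[cbind(round(cloud$v) + 1, round(cloud$u) + 1)])
  # shape mismatch that is not a uniform scaling errors
  expect_error(register_disease(cloud, threshold_disease(
    intensity_image(matrix(0, 300, 401)), 110)), "scaling")
})

test_that("a mask from an upsampled UV frame is registered by NN resampling", {
  fx <- small_fixture()
  cloud <- fx$rec$cloud
  big <- fx$sc$patch_mask[rep(1:300, each = 2), rep(1:400, each = 2)]
  reg <- register_disease(cloud, structure(big, class = c("disease_mask",
                                                          "matrix", "array")))
  expect_equal(reg$disease,
               fx$sc$patch_mask[cbind(round(cloud$v) + 1, round(cloud$u) + 1)])
})

test_that("coverage is the flagged fraction, permutation invariant, bounded", {
  fx <- small_fixture()
  rep0 <- disease_coverage(fx$rec$cloud)
  expect_equal(rep0$coverage_fraction,
               rep0$n_disease_pixels / rep0$n_structure_points)
  perm <- fx$rec$cloud[sample(nrow(fx$rec$cloud)), ]
  expect_equal(disease_coverage(perm)$coverage_fraction,
               rep0$coverage_fraction)
  cl <- fx$rec$cloud
  cl$disease <- FALSE
  expect_equal(disease_coverage(cl)$coverage_fraction, 0)
  cl$disease <- TRUE
  expect_equal(disease_coverage(cl)$coverage_fraction, 1)
  empty <- cl[0, ]
  expect_error(disease_coverage(empty), "empty")
})

test_that("disease reports serialize to JSON with all counts", {
  fx <- small_fixture()
  path <- tempfile(fileext = ".json")
  write_disease_report(fx$rec$report, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n_disease_pixels, fx$rec$report$n_disease_pixels)
  expect_equal(back$n_structure_points, fx$rec$report$n_structure_points)
  expect_equal(back$coverage_fraction, fx$rec$report$coverage_fraction,
               tolerance = 1e-12)
})
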