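test_that("scene generation is reproducible and validates its inputs", {
  a <- make_scene(width = 120, height = 90, seed = 5)
  b <- make_scene(width = 120, height = 90, seed = 5)
  expect_identical(a, b)
  c <- make_scene(width = 120, height = 90, seed = 6)
  expect_false(identical(a$depth, c$depth))
  expect_error(make_scene(depth_range = c(100, 90)), "near < far")
})

test_that("rendered texture has positive ExG on the leaf and zero elsewhere", {
  sc <- make_scene(width = 160, height = 120, seed = 8)
  exg <- 2 * sc$reflectance$green - sc$reflectance$red - sc$reflectance$blue
  expect_true(all(exg[sc$leaf_mask] > 0))
  expect_true(all(abs(exg[!sc$leaf_mask]) < 1e-12))
})

test_that("the fluorescence patch covers the requested leaf fraction", {
  for (p in c(0.02, 0.04, 0.1)) {
    sc <- make_scene(width = 240, height = 180, seed = 9, patch_fraction = p)
    target <- p * sum(sc$leaf_mask)
    expect_lt(abs(sum(sc$patch_mask) - target) / target, 0.01)
    expect_true(all(sc$leaf_mask[sc$patch_mask]))   # patch lies on the leaf
  }
})

test_that("rendered disparity is exactly f_px * baseline / depth", {
  sc <- make_scene(width = 200, height = 150, seed = 10)
  vs <- render_views(sc, baseline = 3)
  fku <- vs$a$fku
  expect_lt(max(abs(vs$a$true_disparity - fku * 3 / vs$a$true_depth)), 1e-9)
  expect_lt(max(abs(vs$b$true_disparity - fku * 3 / vs$b$true_depth)), 1e-9)
  # two planes at Z0 and 2*Z0 disparities are in ratio 2
  zs <- matrix(100, 100, 140); zs[, 71:140] <- 200
  sc2 <- scene_with_depth(zs, seed = 12)
  v2 <- render_views(sc2, baseline = 2)
  expect_equal(v2$a$true_disparity[1, 1] / v2$a$true_disparity[1, 140], 2)
  expect_error(render_views(sc, baseline = -1), "positive")
})

test_that("rendering is seeded and deterministic", {
  sc <- make_scene(width = 100, height = 80, seed = 4)
  v1 <- render_views(sc, baseline = 2)
  v2 <- render_views(sc, baseline = 2)
  expect_identical(unclass(v1$a$frames$green), unclass(v2$a$frames$green))
  expect_identical(unclass(v1$b$frames$green), unclass(v2$b$frames$green))
})

test_that("scene fixtures are written as 7 camera images plus ground truth", {
  sc <- make_scene(width = 80, height = 60, seed = 14)
  vs <- render_views(sc, baseline = 2)
  dir <- tempfile("fixture")
  write_scene_fixture(vs, dir)
  pngs <- list.files(dir, pattern = "\\.png$")
  expect_equal(length(pngs), 7L)    # 2 views x 3 filters + 1 UV frame
  expect_setequal(pngs, c("000_R.png", "000_G.png", "000_B.png",
                          "001_R.png", "001_G.png", "001_B.png",
                          "000_UVG.png"))
  expect_true(file.exists(file.path(dir, "true_depth.tif")))
  expect_true(file.exists(file.path(dir, "scene.json")))
  # frames round-trip through the reader
  fs <- read_frameset(dir, "000")
  expect_equal(unclass(fs$red), unclass(vs$a$frames$red), ignore_attr = TRUE)
  expect_equal(unclass(fs$uv_green), unclass(vs$a$frames$uv_green),
               ignore_attr = TRUE)
})

test_that("turntable rendering at zero rotation reproduces the reference view", {
  sc <- make_scene(width = 120, height = 90, seed = 15)
  seq_v <- render_turntable_sequence(sc, angles = c(0, 2), noise_sd = 0)
  counts <- fluorosfm:::scene_channel_counts(sc)
  expect_lt(mean(abs(unclass(seq_v[[1]]$green) - round(counts$green))), 3.0)
  expect_equal(seq_v[[2]]$view_angle, 2)
  # rotation moves the image: the 2-degree view differs substantially
  expect_gt(mean(abs(unclass(seq_v[[2]]$green) -
                     unclass(seq_v[[1]]$green))), 1.0)
})
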