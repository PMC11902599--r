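# Shared fixtures, built in code and cached across test files.

intr_list <- function(si) {
  list(f = si$f, ku = si$ku, kv = si$kv, u0 = si$u0, v0 = si$v0, s = si$s)
}

synth_config <- function(scene, ...) {
  recon_config(intrinsics = intr_list(synth_intrinsics(scene)),
               upsample_factor = 1L, ...)
}

# Minimal keypoint-set stand-in for matcher/disparity unit tests.
make_kps <- function(u, v, desc = NULL, shape = c(1000L, 1000L)) {
  n <- length(u)
  structure(list(pts = data.frame(u = u, v = v, diameter = 2, angle = 0,
                                  response = 1, octave = 0),
                 desc = if (is.null(desc)) matrix(0, n, 128) else desc,
                 image_shape = shape),
            class = "sift_keypoints")
}

fixture_env <- new.env(parent = emptyenv())

# A small rendered stereo pair plus its full reconstruction, shared by the
# pipeline and fluorescence tests.
small_fixture <- function() {
  if (is.null(fixture_env$rec)) {
    sc <- make_scene(width = 400L, height = 300L, seed = 7L)
    vs <- render_views(sc, baseline = 2)
    cfg <- synth_config(sc)
    fixture_env$sc <- sc
    fixture_env$vs <- vs
    fixture_env$cfg <- cfg
    fixture_env$rec <- suppressMessages(
      reconstruct(vs$a$frames, vs$b$frames, cfg, verbose = FALSE))
  }
  fixture_env
}

# Scene with a hand-set depth field (e.g. a frontoparallel plane), reusing
# the generator's texture machinery.
scene_with_depth <- function(depth, seed = 11L, ...) {
  sc <- make_scene(width = ncol(depth), height = nrow(depth), seed = seed, ...)
  sc$depth <- depth
  sc
}
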