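---
title: "Methods: turntable structure from motion with fluorescence overlay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turntable structure from motion with fluorescence overlay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

A single monochrome camera images a potted plant on a rotation stage
through red, green and blue band-pass filters under white light, and
through the green filter under 365 nm UV excitation.  Two views taken a
small turntable step apart form a quasi-stereo pair: the apparent
horizontal shift (disparity) of a surface feature between the views
encodes its distance from the camera.  `fluorosfm` reconstructs a 3D
point cloud of the plant surface from such a pair and overlays the
UV-induced blue-green fluorescence signal — locally enhanced in tissue
infected by pathogens such as *Bremia lactucae* (lettuce downy mildew) —
onto that surface, ending in a disease surface-coverage statistic.

# Model and procedure

## Spectral channels

Each view consists of three single-channel frames $I(x,y,R)$, $I(x,y,G)$,
$I(x,y,B)$.  Two derived channels are available for feature detection:

* grayscale: the unweighted per-pixel mean of the three frames;
* excess green: $\mathrm{ExG}(x,y) = 2 I(x,y,G) - I(x,y,R) - I(x,y,B)$.

ExG is the default matching channel.  Two properties make it the best
detector input on green tissue: it amplifies leaf-texture contrast
(chlorophyll-rich tissue is green-dominant), and it *cancels achromatic
components exactly* — any signal contributing equally to R, G and B
(ambient light, glare, broadband shading) drops out of $2G - R - B$.
ExG values are kept signed and full-range internally; only
`normalize_for_detection()` produces a detector-ready 8-bit image, by an
affine min–max map to $[0, 255]$ (a constant channel maps to zeros).
Nothing in the acquisition itself fixes how the signed ExG channel
should be quantized before detection; the min–max map is this package's
choice, made because it preserves the contrast ordering and is explicit
and testable.

## Digital upsampling

Frames are enlarged by an integer factor (default 5, turning the native
1080×1440 format into 5400×7200) with Catmull–Rom bicubic convolution
before detection.  Upsampling raises the number of detectable keypoints;
it reproduces source values exactly at the original grid nodes and
constants everywhere.  Output counts are clipped to the source bit-depth
range and rounded.

## Keypoints and matching

Keypoints are SIFT features: extrema of the difference-of-Gaussian scale
space (3 layers per octave, $\sigma_0 = 1.6$), refined to subpixel
position by a quadratic fit, filtered by DoG contrast (0.04 Lowe units)
and edge response (principal-curvature ratio 10), assigned orientations
from a smoothed 36-bin gradient histogram, and described by the 4×4×8
gradient-histogram descriptor (normalized, clipped at 0.2,
renormalized).  Detection is deterministic.

Descriptors of the two views are matched by nearest-neighbour search
with Lowe's ratio test: a pair is kept iff
$d_1/d_2 \le$ `match_ratio` (default 0.6, comparison `<=` at the
boundary).  The default search uses 5 randomized kd-trees in one
approximate index; an exhaustive brute-force mode exists and is the test
oracle for the approximate one.  The search budget (`checks`, default
128 leaf visits per query) is this package's choice — the reference
operating point fixes the index shape (1 kd-tree index, 5 trees) but not
the budget; 128 favours accuracy and makes the search provably
exhaustive (hence exact) on candidate sets of up to 128 descriptors.

## Disparity

For each kept pair the disparity is the horizontal displacement
magnitude $d = |u_b - u_a|$, anchored at the reference-view pixel
$(u_a, v_a)$.  The turntable rotates about a vertical axis, so the
dominant apparent motion is horizontal; signed and absolute disparity
conventions coincide when the rotation direction is fixed, and the
magnitude convention is the one used throughout this package.  Pairs with $d = 0$ are
degenerate and dropped; pairs whose vertical drift $|v_b - v_a|$ exceeds
`max_vertical_drift` (default 20 px at native resolution, scaled by the
upsampling factor) are treated as gross mismatches and dropped.  No
RANSAC is applied by default — the ratio test plus the drift filter is
the method's only outlier rejection; a robust disparity-plane consensus
filter is available behind the `ransac` config flag.  Keypoints found on upsampled frames are rescaled to native pixel
units before any geometry.

## Reprojection

With camera intrinsics $f$ (mm), $k_u, k_v$ (px/mm), principal point
$(u_0, v_0)$ and the calibrated scale factor $s = 0.02$, the 4×4
perspective matrix is

$$
Q = \begin{pmatrix}
1 & 0 & 0 & -u_0\\
0 & -1 & 0 & v_0\\
0 & 0 & s f k_u & 0\\
0 & 0 & 0 & 1
\end{pmatrix},
\qquad
\tilde{P} = Q\, (u, v, 1/d, 1)^\top,
\qquad
(X, Y, Z) = (\tilde X/\tilde W,\ \tilde Y/\tilde W,\ \tilde Z/\tilde W).
$$

Because the last row of $Q$ is $(0,0,0,1)$, $\tilde W = 1$ and the
closed form is $X = u - u_0$, $Y = v_0 - v$, $Z = s f k_u / d$: depth is
inversely proportional to disparity.  The $-1$ in the second row flips
the downward image $v$ axis so world $Y$ points up.  The depth row uses
only $k_u$; the reference camera has square pixels so the asymmetry is
immaterial, and the structure is kept as-is.  The calibrated factor
$s$ acts as a baseline surrogate between the two rotated views and has
no further physical interpretation here, so depths are structure up to
the $s$-controlled scale; an optional `world_scale` factor converts to
physical units as a single multiplication.

## Densification

The sparse cloud (one point per retained match) is expanded to one point
per plant-mask pixel.  Depth is interpolated over the image plane:
piecewise-linear (barycentric over a Delaunay triangulation of the
sample pixels) inside the convex hull of the samples, nearest-sample
outside it.  Linear interpolation reproduces planar depth fields exactly,
which is the oracle the tests use.  Turning a few thousand sparse
matches into a dense surface necessarily adds an interpolation
assumption on top of the measurement; the piecewise-linear choice is
this package's, and `method = "nearest"` is available as the
conservative alternative.

The plant mask defaults to pixels whose lightly smoothed ExG exceeds
`mask_min_exg = 5` counts.  A strict "ExG > 0" rule was considered and
rejected: with zero-mean sensor noise the background ExG distribution is
symmetric around zero, so half the background would enter the mask; 5
counts sits above the noise floor of the ExG combination
($\sqrt{6}\,\sigma \approx 2.5$ counts at $\sigma = 1$) while leaf ExG
values are an order of magnitude larger.

## Fluorescence overlay

The UV-excited green-filter frame contains only fluorescence (the camera
does not see the 365 nm excitation).  Pixels with at least
`disease_threshold` counts (default 110) form the disease mask —
"smaller than 110" is removed, so the boundary value is kept; the
rule fixes only the strict side, so the inclusive keep side is stated
explicitly.  Since the UV frame is taken by the same camera through
the same filter wheel at the same pose, registration onto the cloud is
the identity in pixel space: each point takes the mask value at its
source pixel (a mask whose frame was upsampled is resampled by nearest
neighbour to preserve binarity).  Leaf veins also fluoresce; no vein
suppression is attempted, so vein pixels above the threshold count as
disease, but the threshold is exposed in the config.  The final statistic is
`coverage = flagged points / all points`; the worked numbers 285,771
disease pixels on a 7.2-million-point cloud give 0.0397, reported as 4%
at integer rounding.

# The synthetic scene generator

Real acquisitions are not required for development or testing.
`make_scene()` builds a ground-truth scene parameterized over the
reference-view pixel grid:

* **relief** — a smooth blob-mixture bump field raises "leaves" towards
  the camera above a background plane; `depth_range = c(85, 115)` world
  units by default, a relative depth spread (≈30%) typical of a leafy
  pot plant that fills the frame;
* **texture** — band-limited speckle (Gaussian-smoothed white noise,
  grain 1.5 px) so detectors find features; green reflectance dominates
  on the leaf (ExG > 0 by construction), the background is achromatic
  (ExG = 0);
* **illumination** — a smooth multiplicative field plus a smooth
  *additive achromatic* ambient/glare field.  The additive term cancels
  exactly in ExG but consumes dynamic range in every single channel and
  in grayscale; this is the constructed mechanism that makes ExG the
  best-contrast channel, mirroring the physics that motivates ExG;
* **fluorescence patch** — the $k = \mathrm{round}(p \cdot n_{leaf})$
  leaf pixels closest (in an elliptical metric) to the tallest leaf
  point, with emission 200 counts over a 20-count background, so the
  patch count matches the requested fraction $p$ (default 0.04) exactly
  and the 110-count threshold separates patch from background cleanly.

`render_views()` renders a rectified stereo pair: the second camera is
the first translated by `baseline` (default 2 world units, ≈1 turntable
degree at the default scene depth) along +X, so every pixel obeys
$d = f_{px} b / Z$ exactly — the geometry the Q-matrix model assumes.
Rendering is a z-buffered per-row forward warp; occluded and
off-frame columns are filled from the nearest rendered neighbour in the
row.  Additive Gaussian sensor noise (1 count) is seeded and applied per
view.  All randomness flows from the scene seed.

`render_turntable_sequence()` is the second renderer: a true
small-rotation of the surface about the vertical axis through the
rotation-stage position, forward-warped in 2D with a z-buffer.  It
exists because the angle-step study needs appearance change
(foreshortening, occlusion) that grows with the step — a pure
translation would leave descriptors nearly invariant.  Reconstruction
itself always uses the rectified pair; the rotation renderer
characterizes the matching behaviour versus angle.

What the generator does **not** emulate: real leaf optics (specular
lobes, translucency), radial lens distortion (the real workflow removes
it in calibration), vein fluorescence, defocus, or rolling illumination
changes between filter exposures.  Passing tests on synthetic scenes
therefore validate the pipeline's geometry, matching and bookkeeping —
not its robustness to those physical effects.

# Numerical choices and degenerate inputs

* Ratio test at the boundary: `<=`.  Disease threshold at the boundary:
  kept.
* Bicubic kernel: Catmull–Rom ($a = -0.5$); borders clamped; factor-1
  upsampling is the identity.
* Identical views: every disparity is zero, and reconstruction stops
  with a diagnostic rather than returning an empty cloud (densification
  of nothing is meaningless).
* A missing UV frame downgrades to a structural-only result with a
  warning; the disease flags stay `FALSE` and no report is produced.
* Fewer than 3 disparity samples: linear densification falls back to
  nearest-neighbour with a warning.
* Duplicate sample pixels are deduplicated before triangulation;
  degenerate (collinear) sample sets fall through to nearest-neighbour.
* Matcher determinism: tree construction is seeded (`seed` in the
  config); detection is deterministic by construction.

# Problem sizes used by the test-suite and acceptance script

The worked-example checks run on the printed operating numbers
(7.2-million-point cloud, 1080×1440 frames at factor 5).  The synthetic
round trip runs at 1280×960 (≈1.2 Mpx) — large enough that the disparity
spread across the scene (≈7 px) dominates keypoint localization error —
and the study runners at 400×300 and 320×240, sizes at which the full
suite completes in a few minutes on one core while leaving the measured
statistics (Spearman ρ ≈ 0.97, >95% of matches within 2 px) far from
their acceptance margins.

The angle-step study evaluates steps of 1, 3 and 6 degrees over a
0–8 degree sweep.  Per-pair matched counts fluctuate by roughly ±10%
with the pair's absolute position in the sweep (the synthetic scene is
parameterized in the 0° frame, so views degrade mildly with angle), so
well-separated step sizes are needed for the step effect to stand clear
of that noise; the runner itself accepts any step list a sequence can
represent.

# Known limitations

* The rectified-stereo model is a small-angle approximation of the
  turntable geometry; model error grows with the angle step, which is
  visible in the angle-step study as a falling matched-keypoint count.
* Absolute metric depth is not claimed: $Z = s f k_u / d$ inherits the
  calibrated but physically unexplained scale $s$.
* Only two views are fused; there is no multi-view registration of the
  full 360° sweep, no meshing, and no texture atlas.
* Disease coverage is a point-count ratio over the reconstructed cloud,
  not a physical area; pixels outside the plant mask are not counted on
  either side of the ratio.
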