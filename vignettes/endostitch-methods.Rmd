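---
title: "Methods: scale-invariant stitching of endoscope frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scale-invariant stitching of endoscope frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endostitch)
```

This vignette records the model behind `endostitch`, the assumptions it
makes, and the design decisions taken where the method leaves room. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Model and assumptions

The pipeline assumes the two frames view a *near-planar* patch of
tissue, so that corresponding image points are related by a single 3×3
projective transform `H` with `h33 = 1` (8 free parameters). This is the
standard local model for endoscope mosaics; it degrades gracefully for
shallow relief but cannot represent strong parallax, fluid motion, or
deformation between frames. Photometrically it assumes the two
exposures differ by at most a smooth gain/offset — the descriptor is
built from gradients and normalized, so it is exactly invariant to
affine brightness changes (one of the unit tests asserts this to 1e-6).

### Detection

Keypoints are extrema of the difference-of-Gaussians stack. Parameters,
with units and defaults:

| parameter | default | meaning / why |
|---|---|---|
| `sigma0` | 1.6 px | base blur of the first layer; the conventional operating point that balances keypoint yield against noise sensitivity |
| `intervals` | 3 | scale samples per octave doubling; layers per octave = `intervals + 3` so every interval has a complete 3-layer neighbourhood |
| `k` | `2^(1/intervals)` | scale step; `k = 2` is sometimes quoted for this detector but contradicts the small-`(k−1)` Laplacian approximation the method itself relies on, so it is selectable (`pipeline_config(k = 2)`) rather than default |
| `assumed_blur` | 0.5 px | smoothing attributed to the camera; the first layer is blurred by `sqrt(sigma0² − assumed_blur²)` |
| `contrast_threshold` | 0.03 | minimum interpolated `abs(D(x̂))` on the `[0, 1]` intensity scale — inputs are normalized exactly so this threshold is meaningful |
| `gamma` | 10 | maximum principal-curvature ratio; bound `(γ+1)²/γ = 12.1` |
| octaves | `floor(log2(min(h, w))) − 3` | capped so the coarsest octave keeps ≥ 8 px on its short side |

There is no initial 2× upsampling by default (`upsample = TRUE`
restores it). Derivatives are unit-spacing central differences;
refinement re-centres when any offset component exceeds 0.5 and gives
up after 5 moves; candidates whose 3-D Hessian is singular or that
wander out of the stack are dropped.

### Description

Orientation uses a 36-bin histogram over a radius `3·1.5σ` circle,
magnitudes weighted by a Gaussian of std `1.5σ` (the method fixes the
circle radius but not the weight width; `1.5σ` is the conventional
choice). The raw histogram gets two passes of a circular 3-point box
smoother before peak picking — without it the winning bin jitters
between neighbours under resampling and the assigned orientation (hence
the descriptor) is unstable. Auxiliary orientations are emitted for
local maxima at ≥ 80% of the global peak; peak angles are refined
parabolically, ties to the lower bin.

The descriptor is 4×4 cells of side `3σ` × 8 orientation bins with
trilinear interpolation. The spatial Gaussian weight is specified in
the literature as "6σ" with the variance/standard-deviation distinction
left open; read as a standard deviation it coincides with the
conventional half-window width (window = 4 cells × 3σ = 12σ), so the
two candidate readings agree and no option is needed. The sampling
radius is the 4-cell window enlarged by `sqrt(2)` as rotation slack. After L2 normalization, components are
clamped at 0.2 and the vector renormalized (the clamp is stated by the
method; the final renormalization is the convention that keeps the
vector unit-length).

### Matching and purification

2-NN search is a KD-tree (split at the median of the widest dimension,
one descriptor per leaf) queried best-bin-first under a 200-leaf
budget. The method's wall-clock cut-off is replaced by this
deterministic budget: a timeout is untestable. All ties break to the
lower index so every search is reproducible; with an unlimited budget
BBF provably equals the exhaustive scan (asserted exactly in the
tests, including tie-breaks, because both sides share one distance
kernel).

Purification: ratio screen at `T_R = 0.65` (strict `R < T_R`) in both
directions, bidirectional intersection, then RANSAC with 4-pair
samples. The inlier threshold is `t² = qchisq(0.99, 2)·σ²` with
`σ = 1 px` assumed localization noise. The outlier fraction is
re-estimated after every improved consensus (`ε̂ = 1 − X/n`) and the
required iteration count recomputed; the search also stops after 200
iterations without improvement — the concrete form of the "inlier
count no longer increases" stopping note. Samples whose any triple has
twice-triangle-area below `1e-6` of the squared bounding-box diagonal
are redrawn as collinear. The final model is refit by least squares on
the consensus set, iterating refit ↔ re-classify to a fixed point (at
most 10 rounds) so the result does not depend on which minimal sample
happened to win.

Image-match verification uses the linear rule `n_i > 8.0 + 0.3·n_f`.
The underlying binomial posterior needs the per-match inlier
probabilities `p1` (true overlap) and `p0` (no overlap), which the
method never prints; `p1 = 0.6`, `p0 = 0.1` are used for the reported
posterior, which is diagnostic only — acceptance is decided by the
linear rule alone, so these defaults cannot change a decision.

### Estimation and fusion

`solve_dlt` builds the `2n×8` system in `h11…h32` and solves by QR. By
default both point sets are Hartley-normalized (centroid 0, mean
distance √2) and the result denormalized; the raw normal-equation path
`(XᵀX)⁻¹Xᵀy` is numerically fragile at image-scale coordinates but
exactly reproducible with `normalize = FALSE`, and the tests confirm
both give the same residual on well-conditioned data. Fixing `h33 = 1`
fails when the true `h33 ≈ 0` (frame planes near right angles) — a
documented limitation irrelevant to endoscope motion.

Fusion warps frame 2 through `H⁻¹` (backward mapping, bilinear) and
feathers the overlap with `d1` ramping linearly 1→0 along the dominant
displacement axis, per row (or column), `d2 = 1 − d1`. A circulating
variant of the fusion formula halves the blended overlap term, which
contradicts the constraint `d1 + d2 = 1` and would darken the seam; the
default omits the halving and `literal_overlap_halving = TRUE`
reproduces the halved variant. A chamfer-distance-transform weight
(`blend_mode = "distance"`) is available for irregular overlaps.

## The synthetic generator

`generate_pair()` emulates what matters about endoscope frames for this
pipeline: a textured near-planar surface (multi-octave value noise with
a 2.5× contrast stretch), a sparse field of Gaussian spots standing in
for the distinct blob structure of tissue — vessel junctions, speckle —
(about 240 spots on a 200×200 frame, std 2–7 px, amplitude 0.25–0.55
of the intensity range), a circular field-of-view vignette (radius 0.95
of the half-frame, smoothstep falloff), per-view photometric jitter
(gain ±5%, offset ±0.02) and additive Gaussian sensor noise
(sd 0.02 on `[0, 1]`). Both views are sampled bilinearly from a 1.6×
oversampled latent scene so that neither frame is privileged with
pixel-exact texture — two exposures of the same continuous surface.
Without the spot field, value noise alone produces only shallow, broad
scale-space extrema whose existence flips under viewpoint change; real
tissue is not like that, and the spot field restores realistic detector
repeatability. The stretch exists for the same reason: raw value noise
is far flatter than tissue imagery and leaves most DoG responses below
the fixed 0.03 contrast cut.

What the generator does *not* model: specular highlights, radial lens
distortion, depth parallax, motion blur, and fluid/deformation between
frames. Passing tests therefore demonstrate correctness of the
geometry/matching chain under the planar-projective assumption, not
robustness to those physical effects.

`generate_matches()` plants labelled correspondence sets for the
purification benchmark: inliers are points mapped by `H_true` plus
Gaussian localization noise (σ = 1 px) with highly similar planted
descriptors (cosine 0.95–0.99); outliers model descriptor confusions on
repetitive texture — half are "near misses" displaced up to 12 px from
the true mapping, half uniform clutter, all with only moderately
similar descriptors (cosine 0.30–0.70). The near-miss population is
essential: purely uniform mismatches are almost never consistent with
any homography, so RANSAC alone would already achieve ~100% precision
and the three-column comparison (before / RANSAC-only / improved) that
motivates the two-stage cascade would be vacuous. Near-miss confusions
are exactly the mismatches repetitive tissue produces and exactly the
ones the ratio screen removes but a geometric consensus cannot.

## Numerical choices

- Gaussian kernels truncated at `4σ`, borders mirror-reflected; a
  normalized kernel keeps constant images constant to machine
  precision.
- `detect_extrema` ignores samples with `abs(D) < 1e-12`: separable
  convolution leaves ~1e-16 float noise on an exactly constant image,
  ten orders of magnitude below usable contrast.
- Degenerate second-nearest distances (`d2 = 0`, duplicate descriptors)
  are rejected by the ratio screen with a warning.
- The RANSAC sampler draws from one seeded generator injected through
  the configuration (`seed = 0` default); generators save and restore
  the caller's RNG state.
- Coordinates are 0-based, `x` = column, `y` = row (y down), pixel
  centres at integers. All angles in degrees in `[0, 360)`,
  `θ = atan2(dy, dx)` — atan2 settles the quadrant the bare arctan
  ratio leaves open.

## Problem sizes

The shipped tests and the acceptance script use 200×200 synthetic
frames (about 150 keypoints each), 20-seed medians for end-to-end
recovery, planted sets of 120 inliers + 80 outliers for the
purification benchmark, and 500-descriptor pools for matcher checks —
sizes chosen so the full suite exercises every stage in a few minutes
on one core while leaving each statistic comfortably away from its
decision boundary.

## Known limitations

- Pairwise registration only: chaining many frames accumulates error;
  no global bundle adjustment.
- The planar-projective model ignores parallax and deformation.
- `h33 = 1` parameterization (see above).
- BBF recall under a fixed budget depends on the descriptor
  distribution; the 200-leaf budget is honest about being approximate,
  and the exact matcher is one flag away (`matcher = "brute"`).
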