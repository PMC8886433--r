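# endostitch

Feature-based mosaicking of overlapping endoscope frames in R.

Endoscopes trade field of view for magnification: a frame that is sharp
enough to judge a lesion rarely shows its full extent. Stitching
consecutive frames into one panorama restores the context, but
endoscopic tissue is full of locally similar texture, so naive feature
matching produces many false correspondences and a warped mosaic. This
package implements a scale-invariant feature pipeline whose distinctive
part is a **two-stage purification of tentative matches**: a
bidirectional nearest-neighbour distance-ratio screen followed by
adaptive RANSAC with a χ²-derived inlier threshold and a binomial test
that decides whether the two frames genuinely overlap at all.

It is aimed at researchers in biomedical image analysis who want an
inspectable, fully scriptable reference implementation of this pipeline —
every stage is an exported function with a testable contract, and a
bundled synthetic generator of endoscope-like frames makes the whole
chain reproducible without any external data.

## The method

For frames `I1`, `I2` (grayscale in `[0, 1]`):

1. **Detection.** Gaussian scale space `L(x, y, σ) = G(σ) * I` with
   `intervals + 3` layers per octave, `σ_j = σ0 k^(j-1)`, `σ0 = 1.6`,
   `k = 2^(1/3)`; difference-of-Gaussians layers `D = L(kσ) − L(σ)`.
   Candidates are 26-neighbour extrema of `D`, refined by solving
   `x̂ = −(∂²D/∂x²)⁻¹ ∂D/∂x`; keypoints need `|D(x̂)| ≥ 0.03` and pass
   the principal-curvature edge test
   `Tr(H)²/Det(H) < (γ+1)²/γ` with `γ = 10`.
2. **Description.** 36-bin gradient-orientation histogram in a radius
   `3·1.5σ` window assigns the main orientation θ (auxiliary
   orientations at ≥ 80% of the peak); the descriptor is the classic
   4×4 spatial grid × 8 orientation bins = 128-vector, L2-normalized,
   clamped at 0.2, renormalized.
3. **Matching.** 2-nearest-neighbour search with a KD-tree queried
   best-bin-first under a 200-leaf budget (exact brute force available
   as an oracle).
4. **Purification.** Keep forward matches with ratio `R = d1/d2 < 0.65`
   (set A), likewise backward (set B), intersect bidirectionally
   (set C). Run RANSAC on C: 4-pair samples, adaptive iteration count
   `N = log(1−p)/log(1−(1−ε)⁴)` at `p = 0.99`, inliers at squared
   transfer error below `t² = χ²₂(0.99)·σ² ≈ 9.21 σ²`. Accept the image
   match only if the inlier count satisfies `n_i > 8.0 + 0.3 n_f`.
5. **Estimation and fusion.** The homography (8 free parameters,
   `h33 = 1`) is refit on the consensus set by least squares on the
   `2n×8` DLT system; frame 2 is warped into frame 1's plane and the
   overlap blended with gradual-in/gradual-out feathering
   (`d1` ramps 1→0 across the overlap, `d1 + d2 = 1`).

## Worked example

```r
library(endostitch)

# synthetic endoscope pair: same scene, camera shifted (+40, +5) px
pair <- generate_pair(scene_spec(seed = 1), translation_homography(40, 5))
res  <- stitch_images(pair$img1, pair$img2)
res
#> stitch: 149/146 keypoints; m1 = 61, m2 = 59, m3 = 58; inliers n_i = 58 -> ACCEPTED
round(res$H, 4)
#>        [,1]    [,2]    [,3]
#> [1,] 1.0058 -0.0016 39.9949
#> [2,] 0.0039  1.0008  4.8276
#> [3,] 0.0000  0.0000  1.0000
```

Reading the report: 149 and 146 keypoints were detected in the two
frames; the bidirectional ratio screen kept 61 forward and 59 backward
matches whose intersection C held `m3 = 58` pairs, all 58 of which
survived RANSAC (`n_i = 58`), comfortably clearing the acceptance rule
`n_i > 8 + 0.3·58 ≈ 25.4`. The estimated transform recovers the planted
translation `(40, 5)` to a few hundredths of a pixel in the linear part;
`res$mosaic$image` holds the blended panorama.

The same pipeline from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "endostitch.R", package = "endostitch"))')
Rscript $CLI simulate --seed 1 --tx 40 -o demo/
Rscript $CLI stitch demo/img1.png demo/img2.png -o demo/mosaic.png \
        --report demo/report.json --homography demo/H.txt
Rscript $CLI bench --seeds 20 -o demo/bench.tsv
```

Exit codes: 0 stitched, 2 overlap verification rejected (no mosaic
written), 1 error.

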