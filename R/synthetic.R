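# Synthetic endoscope-like fixtures: textured image pairs under a known
# homography, and planted correspondence sets with controlled outlier
# contamination.  Every generator is a pure function of its seed and
# spec, so fixtures are rebuilt in code instead of being shipped.

#' Specification of a synthetic endoscope scene
#'
#' The scene is multi-octave band-limited value noise (texture density
#' controllable, unlike natural images) overlaid with a sparse field of
#' Gaussian spots - the distinct blob structure (vessel junctions,
#' speckle) that real tissue has and that smooth value noise alone
#' lacks; without it scale-space extrema are shallow and flip under
#' viewpoint change.  The scene is seen through a circular field-of-view
#' vignette with a smoothstep falloff, the dark surround characteristic
#' of endoscope frames.  The second view gets a photometric gain/offset
#' jitter and additive Gaussian sensor noise.
#'
#' @param seed integer; all randomness derives from it.
#' @param size `c(h, w)` in px (default 200 x 200, a small endoscope
#'   frame).
#' @param texture_octaves,persistence value-noise octave count and
#'   amplitude decay per octave.
#' @param texture_contrast linear contrast stretch applied to the latent
#'   scene about mid-gray (clipped to `[0, 1]`).  Raw value noise is much
#'   flatter than tissue imagery; the stretch restores realistic local
#'   contrast so blob responses clear the detector's 0.03 contrast cut.
#' @param spot_density Gaussian spots per view pixel (default 0.006,
#'   about 240 spots on a 200 x 200 frame).
#' @param spot_amplitude,spot_sigma ranges of spot amplitude (sign
#'   randomized) and std in latent-scene pixels.
#' @param vignette_radius field-of-view radius as a fraction of the
#'   half-diagonal-free half-size (default 0.95).
#' @param vignette_softness falloff width as a fraction of the radius.
#' @param gain_jitter,offset_jitter photometric jitter half-ranges for
#'   the second view (uniform in +/- the value).
#' @param noise_sd additive Gaussian noise std on `[0, 1]` intensities
#'   (default 0.02, a realistic sensor-noise level).
#' @return list of class `"scene_spec"`.
#' @export
scene_spec <- function(seed = 1L, size = c(200L, 200L), texture_octaves = 5L,
                       persistence = 0.8, texture_contrast = 2.5,
                       spot_density = 0.006, spot_amplitude = c(0.25, 0.55),
                       spot_sigma = c(2, 7), vignette_radius = 0.95,
                       vignette_softness = 0.2, gain_jitter = 0.05,
                       offset_jitter = 0.02, noise_sd = 0.02) {
  stopifnot(length(size) == 2, all(size >= 32), texture_octaves >= 1,
            persistence > 0, texture_contrast > 0, spot_density >= 0,
            vignette_radius > 0, noise_sd >= 0)
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 texture_octaves = as.integer(texture_octaves),
                 persistence = persistence,
                 texture_contrast = texture_contrast,
                 spot_density = spot_density,
                 spot_amplitude = spot_amplitude, spot_sigma = spot_sigma,
                 vignette_radius = vignette_radius,
                 vignette_softness = vignette_softness,
                 gain_jitter = gain_jitter, offset_jitter = offset_jitter,
                 noise_sd = noise_sd),
            class = "scene_spec")
}

# multi-octave value noise on an h x w grid, normalized to [0, 1];
# consumes the caller's RNG stream
value_noise <- function(h, w, octaves = 4L, persistence = 0.55) {
  acc <- matrix(0, h, w)
  amp <- 1
  for (o in seq_len(octaves)) {
    gn <- 2^(o + 1)  # grid cells per axis at this octave
    grid <- matrix(runif((gn + 1)^2), gn + 1, gn + 1)
    gx <- (seq_len(w) - 1) / (w - 1) * gn
    gy <- (seq_len(h) - 1) / (h - 1) * gn
    layer <- matrix(
      bilinear_sample(grid, rep(gx, each = h), rep(gy, times = w))$values,
      h, w)
    acc <- acc + amp * layer
    amp <- amp * persistence
  }
  rng <- range(acc)
  (acc - rng[1]) / max(rng[2] - rng[1], 1e-12)
}

smoothstep <- function(edge0, edge1, x) {
  t <- pmin(pmax((x - edge0) / (edge1 - edge0), 0), 1)
  t * t * (3 - 2 * t)
}

# circular field-of-view weight for an h x w frame
vignette_mask <- function(h, w, radius_frac, softness) {
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  r0 <- radius_frac * min(h, w) / 2
  x <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  y <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  1 - smoothstep(r0 * (1 - softness), r0, r)
}

#' Generate a synthetic overlapping image pair
#'
#' Renders one latent textured scene at 1.6x resolution and samples both
#' views from it - view 1 through a pure scaling, view 2 through the
#' scaling composed with the inverse of `H_true` (so `H_true` maps
#' view-1 coordinates to view-2 coordinates, the direction the pipeline
#' estimates).  Sampling both views bilinearly from the oversampled
#' latent scene mimics two camera exposures of the same continuous
#' surface: neither frame is privileged with pixel-exact texture.  Each
#' view is then vignetted in its own frame, view 2 gets the photometric
#' jitter, and both get additive noise.  Deterministic given the spec's
#' seed.
#'
#' @param spec a [scene_spec()].
#' @param H_true 3x3 homography, view-1 to view-2 coordinates; it must
#'   keep at least 25% of view 1 visible in view 2.
#' @return list: `img1`, `img2` (matrices in `[0, 1]`), `H_true`, `spec`.
#' @export
generate_pair <- function(spec, H_true = translation_homography(30, 0)) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  # overlap precondition: fraction of view-1 samples landing inside view 2
  gx <- seq(0, w - 1, length.out = 24)
  gy <- seq(0, h - 1, length.out = 24)
  pts <- cbind(rep(gx, each = length(gy)), rep(gy, times = length(gx)))
  mp <- apply_homography(H_true, pts)
  frac <- mean(mp[, 1] >= 0 & mp[, 1] <= w - 1 & mp[, 2] >= 0 & mp[, 2] <= h - 1)
  if (frac < 0.25)
    stop("H_true keeps only ", round(100 * frac), "% of view 1 visible in ",
         "view 2 (< 25%): pair not stitchable by design")
  with_seed(spec$seed, {
    over <- 1.6  # latent-scene oversampling factor
    hs <- ceiling(over * h) + 2L; ws <- ceiling(over * w) + 2L
    scene <- value_noise(hs, ws, spec$texture_octaves, spec$persistence)
    scene <- pmin(pmax((scene - 0.5) * spec$texture_contrast + 0.5, 0), 1)
    n_spots <- round(spec$spot_density * h * w)
    if (n_spots > 0) {
      for (i in seq_len(n_spots)) {
        cx <- runif(1, 0, ws - 1); cy <- runif(1, 0, hs - 1)
        s <- runif(1, spec$spot_sigma[1], spec$spot_sigma[2])
        a <- runif(1, spec$spot_amplitude[1], spec$spot_amplitude[2]) *
          sample(c(-1, 1), 1)
        r <- ceiling(4 * s)
        rows <- max(1, round(cy) + 1 - r):min(hs, round(cy) + 1 + r)
        cols <- max(1, round(cx) + 1 - r):min(ws, round(cx) + 1 + r)
        scene[rows, cols] <- scene[rows, cols] +
          a * exp(-(outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, "+")) / (2 * s^2))
      }
      scene <- pmin(pmax(scene, 0), 1)
    }
    xs <- rep(seq_len(w) - 1, each = h)
    ys <- rep(seq_len(h) - 1, times = w)
    img1 <- matrix(bilinear_sample(scene, over * xs, over * ys)$values, h, w)
    Hi <- solve(H_true); Hi <- Hi / Hi[3, 3]
    den <- Hi[3, 1] * xs + Hi[3, 2] * ys + Hi[3, 3]
    img2 <- matrix(bilinear_sample(scene,
                                   over * (Hi[1, 1] * xs + Hi[1, 2] * ys + Hi[1, 3]) / den,
                                   over * (Hi[2, 1] * xs + Hi[2, 2] * ys + Hi[2, 3]) / den)$values,
                   h, w)
    gain <- 1 + runif(1, -spec$gain_jitter, spec$gain_jitter)
    offs <- runif(1, -spec$offset_jitter, spec$offset_jitter)
    img2 <- img2 * gain + offs
    vig <- vignette_mask(h, w, spec$vignette_radius, spec$vignette_softness)
    img1 <- img1 * vig
    img2 <- img2 * vig
    if (spec$noise_sd > 0) {
      img1 <- img1 + rnorm(h * w, sd = spec$noise_sd)
      img2 <- img2 + rnorm(h * w, sd = spec$noise_sd)
    }
    list(img1 = pmin(pmax(img1, 0), 1), img2 = pmin(pmax(img2, 0), 1),
         H_true = H_true, spec = spec)
  })
}

#' Specification of a planted correspondence set
#'
#' Models the match population the purification cascade sees on
#' endoscopic frames.  Inlier pairs are points mapped by `H_true` plus
#' Gaussian localization noise, with highly similar planted descriptors.
#' Outliers (descriptor confusions) come in two flavours reflecting how
#' mismatches arise on repetitive tissue texture: a `confusion_fraction`
#' of "near misses" displaced from the true mapping by up to
#' `confusion_radius` px (these are what geometric consensus alone
#' struggles to reject), the rest uniform clutter over the frame;
#' both get only moderately similar descriptors, so their
#' nearest/second-nearest distance ratio is high.
#'
#' @param n_inliers,n_outliers population sizes (defaults 120 / 80).
#' @param H_true 3x3 ground-truth homography.
#' @param noise_sigma inlier localization std in px (default 1).
#' @param range `c(w, h)` coordinate range (default 200 x 200).
#' @param confusion_fraction share of outliers that are near misses
#'   (default 0.5).
#' @param confusion_radius maximum near-miss displacement in px
#'   (default 12).
#' @param desc_dim planted descriptor dimension (default 128).
#' @param inlier_similarity,outlier_similarity cosine-similarity ranges
#'   of planted descriptor pairs.
#' @param seed integer seed.
#' @return list of class `"planted_match_spec"`.
#' @export
planted_match_spec <- function(n_inliers = 120L, n_outliers = 80L,
                               H_true = translation_homography(25, 10),
                               noise_sigma = 1, range = c(200, 200),
                               confusion_fraction = 0.5,
                               confusion_radius = 12, desc_dim = 128L,
                               inlier_similarity = c(0.95, 0.99),
                               outlier_similarity = c(0.30, 0.70),
                               seed = 1L) {
  stopifnot(n_inliers >= 0, n_outliers >= 0, n_inliers + n_outliers >= 4,
            noise_sigma >= 0)
  structure(list(n_inliers = as.integer(n_inliers),
                 n_outliers = as.integer(n_outliers), H_true = H_true,
                 noise_sigma = noise_sigma, range = range,
                 confusion_fraction = confusion_fraction,
                 confusion_radius = confusion_radius,
                 desc_dim = as.integer(desc_dim),
                 inlier_similarity = inlier_similarity,
                 outlier_similarity = outlier_similarity,
                 seed = as.integer(seed)),
            class = "planted_match_spec")
}

# unit vector with a given cosine similarity to unit vector u
similar_unit_vector <- function(u, cos_sim) {
  r <- rnorm(length(u))
  r <- r - sum(r * u) * u
  r <- r / sqrt(sum(r^2))
  cos_sim * u + sqrt(max(1 - cos_sim^2, 0)) * r
}

#' Generate a labelled planted correspondence set
#'
#' @param spec a [planted_match_spec()].
#' @return list: `pairs` (data frame `p`, `q`, `x1`, `y1`, `x2`, `y2`,
#'   `inlier`), descriptor matrices `desc1`, `desc2` (row i belongs to
#'   point i of the respective image), `H_true`, and the `spec`.
#' @export
generate_matches <- function(spec) {
  stopifnot(inherits(spec, "planted_match_spec"))
  n_in <- spec$n_inliers; n_out <- spec$n_outliers
  n <- n_in + n_out
  with_seed(spec$seed, {
    x1 <- runif(n, 0, spec$range[1]); y1 <- runif(n, 0, spec$range[2])
    mp <- apply_homography(spec$H_true, cbind(x1, y1))
    x2 <- numeric(n); y2 <- numeric(n)
    if (n_in > 0) {
      i <- seq_len(n_in)
      x2[i] <- mp[i, 1] + rnorm(n_in, sd = spec$noise_sigma)
      y2[i] <- mp[i, 2] + rnorm(n_in, sd = spec$noise_sigma)
    }
    if (n_out > 0) {
      o <- seq.int(n_in + 1L, n)
      n_conf <- round(spec$confusion_fraction * n_out)
      conf <- head(o, n_conf)
      unif <- setdiff(o, conf)
      if (length(conf)) {
        ang <- runif(length(conf), 0, 2 * pi)
        rad <- runif(length(conf), 0, spec$confusion_radius)
        x2[conf] <- mp[conf, 1] + rad * cos(ang)
        y2[conf] <- mp[conf, 2] + rad * sin(ang)
      }
      if (length(unif)) {
        x2[unif] <- runif(length(unif), 0, spec$range[1])
        y2[unif] <- runif(length(unif), 0, spec$range[2])
      }
    }
    desc1 <- matrix(rnorm(n * spec$desc_dim), n, spec$desc_dim)
    desc1 <- desc1 / sqrt(rowSums(desc1^2))
    sims <- c(runif(n_in, spec$inlier_similarity[1], spec$inlier_similarity[2]),
              runif(n_out, spec$outlier_similarity[1], spec$outlier_similarity[2]))
    desc2 <- t(vapply(seq_len(n),
                      function(i) similar_unit_vector(desc1[i, ], sims[i]),
                      numeric(spec$desc_dim)))
    pairs <- data.frame(p = seq_len(n), q = seq_len(n),
                        x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                        inlier = seq_len(n) <= n_in)
    list(pairs = pairs, desc1 = desc1, desc2 = desc2,
         H_true = spec$H_true, spec = spec)
  })
}
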