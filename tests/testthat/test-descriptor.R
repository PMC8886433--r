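test_that("gradient field matches the analytic gradient of ramps", {
  n <- 32
  # horizontal ramp: gradient along +x, theta = 0, constant magnitude
  L <- matrix(rep((0:(n - 1)) / n, each = n), n, n)
  g <- gradient_field(L)
  inner <- g$theta[3:(n - 2), 3:(n - 2)]
  expect_equal(max(abs(inner)), 0)
  expect_equal(sd(g$mag[3:(n - 2), 3:(n - 2)]), 0)
  expect_equal(g$mag[10, 10], 2 / n)  # central difference, no /2
  # vertical ramp (y down): theta = 90
  Lv <- matrix(rep((0:(n - 1)) / n, times = n), n, n)
  gv <- gradient_field(Lv)
  expect_equal(max(abs(gv$theta[3:(n - 2), 3:(n - 2)] - 90)), 0)
  # brute-force atan2 oracle on an oblique ramp
  Lo <- (L + 2 * Lv) / 3
  go <- gradient_field(Lo)
  expect_equal(go$theta[15, 15], (atan2(2 / n / 3 * 2, 1 / n / 3 * 2) * 180 / pi) %% 360)
  # constant layer: zero magnitude everywhere
  gc <- gradient_field(matrix(0.7, n, n))
  expect_equal(max(gc$mag), 0)
})

test_that("orientation assignment finds the dominant direction", {
  n <- 33
  # uniform 45-degree gradient: L = (x + y)/c
  L <- outer(0:(n - 1), 0:(n - 1), function(r, c) (r + c) / (4 * n))
  ss <- fake_layer_ss(L)
  okp <- assign_orientations(fake_kp(16, 16), ss)
  expect_equal(nrow(okp), 1)
  expect_lt(abs(okp$theta - 45), 5)  # within half a 10-degree bin
  hist <- orientation_histogram(fake_kp(16, 16), ss)
  expect_length(hist, 36)
})

test_that("two equal orthogonal gradient populations give two orientations", {
  n <- 41; mid <- 21
  # left half: horizontal ramp (theta 0); right half: vertical ramp
  # (theta 90), equal strength
  L2 <- outer(1:n, 1:n, function(r, c) ifelse(c < mid, c, r) / (4 * n))
  okp <- assign_orientations(fake_kp(mid - 1, mid - 1), fake_layer_ss(L2))
  expect_equal(nrow(okp), 2)
  th <- okp$theta
  expect_true(any(pmin(abs(th), abs(th - 360)) < 10))
  expect_true(any(abs(th - 90) < 10))
})

test_that("flat patches emit no orientation", {
  okp <- assign_orientations(fake_kp(16, 16), fake_layer_ss(matrix(0.5, 33, 33)))
  expect_equal(nrow(okp), 0)
})

test_that("rotating the patch rotates the assigned orientation", {
  img <- texture_image(seed = 7, 64, 64)
  ss <- build_scale_space(img, octaves = 1)
  kp <- fake_kp(30, 26, sigma = 1.6 * 2^(1/3), layer = 2L)
  th0 <- assign_orientations(kp, ss)$theta[1]
  rot <- rot90cw(img)                      # (x, y) -> (h-1-y, x)
  ssr <- build_scale_space(rot, octaves = 1)
  kpr <- fake_kp(64 - 1 - 26, 30, sigma = 1.6 * 2^(1/3), layer = 2L)
  th1 <- assign_orientations(kpr, ssr)$theta[1]
  d <- (th1 - th0 - 90) %% 360
  expect_lt(min(d, 360 - d), 10)           # within one bin width
})

test_that("descriptors are 128-d, unit norm, non-negative, clamped at 0.2", {
  img <- texture_image(seed = 3, 96, 96)
  feats <- detect_and_describe(img)
  expect_gt(nrow(feats$descriptors), 10)
  expect_equal(ncol(feats$descriptors), 128)
  norms <- sqrt(rowSums(feats$descriptors^2))
  expect_equal(norms, rep(1, length(norms)), tolerance = 1e-6)
  expect_true(all(feats$descriptors >= 0))
  # the pre-renormalization buffer respects the clamp exactly
  ss <- build_scale_space(img)
  okps <- assign_orientations(detect_keypoints(img), ss)
  d <- compute_descriptor(okps[1, ], ss)
  expect_true(all(attr(d, "clamped") <= 0.2 + 1e-12))
  expect_length(attr(d, "raw"), 128)
})

test_that("descriptors are exactly invariant to affine brightness changes", {
  img <- texture_image(seed = 4, 64, 64)
  img2 <- 0.5 * img + 0.25  # gain + offset, stays inside [0, 1]
  ss1 <- build_scale_space(img, octaves = 1)
  ss2 <- build_scale_space(img2, octaves = 1)
  okp <- fake_kp(32, 30, sigma = 1.6 * 2^(1/3), layer = 2L, theta = 30)
  d1 <- compute_descriptor(okp, ss1)
  d2 <- compute_descriptor(okp, ss2)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-6)
})

test_that("descriptors are stable under 90-degree rotation", {
  img <- texture_image(seed = 8, 80, 80)
  feats <- detect_and_describe(img)
  rot <- rot90cw(img)
  ssr <- build_scale_space(rot)
  n <- min(nrow(feats$keypoints), 25)
  dists <- rep(NA_real_, n)
  rank_ok <- rep(NA, n)
  for (i in seq_len(n)) {
    kp <- feats$keypoints[i, ]
    kpr <- fake_kp(80 - 1 - kp$y, kp$x, sigma = kp$sigma, layer = kp$layer)
    kpr$octave <- kp$octave
    sc <- 2^(kp$octave - 1)
    kpr$row <- round(kpr$y / sc) + 1L; kpr$col <- round(kpr$x / sc) + 1L
    okr <- assign_orientations(kpr, ssr)
    if (!nrow(okr)) next
    # compare against the best of the rotated keypoint's orientations
    # (a multi-peak keypoint legitimately carries several descriptors)
    drs <- lapply(seq_len(nrow(okr)),
                  function(j) compute_descriptor(okr[j, ], ssr))
    drs <- drs[!vapply(drs, is.null, logical(1))]
    if (!length(drs)) next
    dd <- vapply(drs, function(d) sqrt(sum((feats$descriptors[i, ] - d)^2)),
                 numeric(1))
    dr <- drs[[which.min(dd)]]
    dists[i] <- min(dd)
    other <- sqrt(rowSums(sweep(feats$descriptors[-i, , drop = FALSE], 2,
                                as.numeric(dr))^2))
    rank_ok[i] <- mean(dists[i] < other) >= 0.95
  }
  expect_lt(median(dists, na.rm = TRUE), 0.35)
  expect_gt(mean(rank_ok, na.rm = TRUE), 0.8)
})

test_that("most keypoints match their true counterpart under a similarity warp", {
  # evaluated over keypoints that HAVE a counterpart: both inside the
  # solid field of view and re-detected within 2 px in the other frame -
  # a keypoint the detector did not find again has no true counterpart
  # for its descriptor to select
  H <- similarity_homography(angle = 10, scale = 1, tx = 15, ty = 5,
                             center = c(80, 80))
  pair <- generate_pair(scene_spec(seed = 11, size = c(160, 160), noise_sd = 0,
                                   gain_jitter = 0, offset_jitter = 0), H)
  f1 <- detect_and_describe(pair$img1)
  f2 <- detect_and_describe(pair$img2)
  mp <- apply_homography(H, as.matrix(f1$keypoints[, c("x", "y")]))
  r1 <- sqrt((f1$keypoints$x - 79.5)^2 + (f1$keypoints$y - 79.5)^2)
  rm <- sqrt((mp[, 1] - 79.5)^2 + (mp[, 2] - 79.5)^2)
  gap <- outer(mp[, 1], f2$keypoints$x, "-")^2 +
         outer(mp[, 2], f2$keypoints$y, "-")^2
  eligible <- r1 < 58 & rm < 58 & sqrt(apply(gap, 1, min)) < 2
  nn <- brute_force_knn(f2$descriptors, f1$descriptors)
  err <- sqrt((f2$keypoints$x[nn$q] - mp[, 1])^2 +
              (f2$keypoints$y[nn$q] - mp[, 2])^2)
  expect_gt(sum(eligible), 20)
  expect_gt(mean(err[eligible] < 3), 0.8)
})
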