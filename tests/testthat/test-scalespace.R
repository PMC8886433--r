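test_that("scale space has the required layer structure and sigma ladder", {
  img <- texture_image(seed = 2, 64, 64)
  ss <- build_scale_space(img, intervals = 3)
  expect_length(ss$gaussian[[1]]$layers, 6)   # intervals + 3
  expect_length(ss$dog[[1]]$layers, 5)        # one fewer
  sig <- ss$gaussian[[1]]$sigmas
  expect_equal(sig[-1] / sig[-length(sig)], rep(ss$k, 5))
  expect_true(all(diff(sig) > 0))
  # successive octaves downsampled by 2
  d1 <- dim(ss$gaussian[[1]]$layers[[1]])
  d2 <- dim(ss$gaussian[[2]]$layers[[1]])
  expect_equal(d2, ceiling(d1 / 2))
  # k = 2 remains selectable
  ss2 <- build_scale_space(img, k = 2, octaves = 2)
  expect_equal(ss2$gaussian[[1]]$sigmas[2] / ss2$gaussian[[1]]$sigmas[1], 2)
})

test_that("too many octaves is an explicit error naming the feasible count", {
  img <- matrix(0.5, 32, 32)
  expect_error(build_scale_space(img, octaves = 7), "at most")
  expect_silent(build_scale_space(img, octaves = max_octaves(img)))
})

test_that("DoG of a constant image is identically zero and yields no extrema", {
  img <- matrix(0.5, 48, 48)
  ss <- build_scale_space(img)
  for (o in seq_along(ss$dog))
    for (D in ss$dog[[o]]$layers)
      expect_equal(max(abs(D)), 0)
  expect_equal(nrow(detect_extrema(ss)), 0)
})

test_that("blob DoG response peaks at the layer the closed form predicts", {
  s <- 4
  img <- blob_image(64, 64, s = s, amp = 0.6)
  ss <- build_scale_space(img, octaves = 2)
  ctr <- c(32, 32)  # 1-based row/col of the blob centre (0-based 31.5 -> 32)
  sig <- ss$dog[[1]]$sigmas
  resp <- vapply(ss$dog[[1]]$layers, function(D) abs(D[ctr[1], ctr[2]]),
                 numeric(1))
  # closed-form oracle: a blurred Gaussian blob of std s has centre
  # amplitude s^2/(s^2 + sigma^2), so the DoG centre response at layer j
  # is s^2/(s^2 + (k sigma_j)^2) - s^2/(s^2 + sigma_j^2)
  oracle <- abs(s^2 / (s^2 + (ss$k * sig)^2) - s^2 / (s^2 + sig^2))
  expect_equal(which.max(resp), which.max(oracle))
})

test_that("DoG approximates the scale-normalized Laplacian on a blob", {
  # D_j = L(k s_j) - L(s_j) ~ (k-1) s_j * s_m * Laplacian(L(s_m)) with
  # s_m the midpoint scale (midpoint evaluation of the exact integral
  # representation); checked at the blob centre of the peak layer
  img <- blob_image(64, 64, s = 5, amp = 0.6)
  ss <- build_scale_space(img, octaves = 1)
  resp <- vapply(ss$dog[[1]]$layers, function(D) abs(D[32, 32]), numeric(1))
  j <- which.max(resp)
  sigj <- ss$dog[[1]]$sigmas[j]
  sigm <- (1 + ss$k) / 2 * sigj
  base <- ss$gaussian[[1]]$layers[[1]]
  sig1 <- ss$gaussian[[1]]$sigmas[1]
  Lm <- gaussian_blur(base, sqrt(sigm^2 - sig1^2))
  lap <- Lm[31, 32] + Lm[33, 32] + Lm[32, 31] + Lm[32, 33] - 4 * Lm[32, 32]
  log_resp <- (ss$k - 1) * sigj * sigm * lap
  dog_resp <- ss$dog[[1]]$layers[[j]][32, 32]
  expect_lt(abs(dog_resp - log_resp) / abs(log_resp), 0.05)
})

test_that("a single impulse in one DoG layer is the only extremum", {
  layers <- lapply(1:5, function(l) matrix(0, 15, 15))
  layers[[3]][8, 6] <- 1
  ss <- fake_dog_ss(layers)
  ex <- detect_extrema(ss)
  expect_equal(nrow(ex), 1)
  expect_equal(as.integer(ex[1, c("layer", "row", "col")]), c(3L, 8L, 6L))
  # a negative impulse (minimum) is also reported
  layers[[3]][8, 6] <- -1
  ex <- detect_extrema(fake_dog_ss(layers))
  expect_equal(nrow(ex), 1)
})

test_that("plateaus are excluded by the strict 26-neighbour comparison", {
  layers <- lapply(1:5, function(l) matrix(0, 15, 15))
  layers[[3]][8, 6] <- 1
  layers[[3]][8, 7] <- 1  # equal-valued neighbour
  expect_equal(nrow(detect_extrema(fake_dog_ss(layers))), 0)
})

test_that("refinement recovers analytic quadratic peaks", {
  # peak exactly on the sample
  ss <- fake_dog_ss(quad_dog_stack(offset = c(0, 0, 0)))
  kp <- refine_keypoint(list(octave = 1L, layer = 3L, row = 6L, col = 6L), ss)
  expect_s3_class(kp, "data.frame")
  expect_equal(c(kp$off_x, kp$off_y, kp$off_s), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(kp$contrast, 0.1, tolerance = 1e-12)
  # analytic peak at offset (0.3, -0.2, 0.1): central differences are
  # exact on a separable quadratic
  ss <- fake_dog_ss(quad_dog_stack(offset = c(0.3, -0.2, 0.1)))
  kp <- refine_keypoint(list(octave = 1L, layer = 3L, row = 6L, col = 6L), ss)
  expect_equal(c(kp$off_x, kp$off_y, kp$off_s), c(0.3, -0.2, 0.1),
               tolerance = 1e-6)
  expect_equal(kp$x, 5 + 0.3, tolerance = 1e-6)
  expect_equal(kp$y, 5 - 0.2, tolerance = 1e-6)
})

test_that("refinement rejects low contrast at the 0.03 threshold", {
  ss <- fake_dog_ss(quad_dog_stack(peak = 0.02))
  res <- refine_keypoint(list(octave = 1L, layer = 3L, row = 6L, col = 6L), ss,
                         contrast_threshold = 0.03)
  expect_identical(res, "low contrast")
  ss <- fake_dog_ss(quad_dog_stack(peak = 0.05))
  expect_s3_class(
    refine_keypoint(list(octave = 1L, layer = 3L, row = 6L, col = 6L), ss,
                    contrast_threshold = 0.03),
    "data.frame")
})

test_that("refinement re-centres on large offsets and is idempotent", {
  # true peak 1.3 samples to the right: first solve exceeds 0.5, the
  # candidate moves one column over and converges at +0.3
  ss <- fake_dog_ss(quad_dog_stack(offset = c(1.3, 0, 0)))
  kp <- refine_keypoint(list(octave = 1L, layer = 3L, row = 6L, col = 6L), ss)
  expect_equal(kp$col, 7L)
  expect_equal(kp$off_x, 0.3, tolerance = 1e-6)
  # refining from the converged sample again reproduces the offset
  kp2 <- refine_keypoint(kp, ss)
  expect_lt(max(abs(c(kp2$off_x - kp$off_x, kp2$off_y - kp$off_y,
                      kp2$off_s - kp$off_s))), 1e-9)
})

test_that("singular Hessians are rejected, not fatal", {
  layers <- lapply(1:5, function(l) matrix(0, 11, 11))  # identically flat
  res <- refine_keypoint(list(octave = 1L, layer = 3L, row = 6L, col = 6L),
                         fake_dog_ss(layers))
  expect_identical(res, "singular Hessian")
})

test_that("edge response filter implements the curvature-ratio bound", {
  # D quadratic in (x, y): Dxx = -a, Dyy = -b exactly
  mk <- function(a, b) {
    layers <- lapply(1:3, function(l)
      outer(1:11, 1:11, function(r, c) 1 - (a * (c - 6)^2 + b * (r - 6)^2) / 2))
    fake_dog_ss(layers)
  }
  kp <- data.frame(octave = 1L, layer = 2L, row = 6L, col = 6L)
  # eigenvalue ratio 15: Tr^2/Det = 256/15 ~ 17.07 > 12.1 -> rejected
  expect_false(edge_response_filter(kp, mk(15, 1), gamma = 10))
  # ratio 5: 36/5 = 7.2 < 12.1 -> kept
  expect_true(edge_response_filter(kp, mk(5, 1), gamma = 10))
  # equal curvatures: ratio 4, kept for any gamma > 1 (the bound
  # (gamma+1)^2/gamma equals 4 exactly at gamma = 1 and the test is strict)
  expect_true(edge_response_filter(kp, mk(1, 1), gamma = 1.01))
  expect_true(edge_response_filter(kp, mk(1, 1), gamma = 10))
  # saddle: Det <= 0 -> rejected regardless of gamma
  expect_false(edge_response_filter(kp, mk(1, -1), gamma = 10))
})

test_that("edge filter is monotone in gamma", {
  img <- texture_image(seed = 5, 96, 96)
  ss <- build_scale_space(img)
  kps <- refine_keypoints(detect_extrema(ss), ss)
  gammas <- c(2, 5, 10, 20, 50)
  kept <- lapply(gammas, function(g) edge_response_filter(kps, ss, g))
  for (i in seq_along(gammas)[-1])
    expect_true(all(kept[[i - 1]] <= kept[[i]]))  # raising gamma never rejects
})

test_that("detections correspond across a 2x downsampling", {
  img <- blob_image(128, 128, cx = 63.5, cy = 63.5, s = 6, amp = 0.6)
  half <- img[seq(1, 127, 2), seq(1, 127, 2)]
  kf <- detect_keypoints(img)
  kh <- detect_keypoints(half)
  bf <- kf[which.max(abs(kf$contrast)), ]
  bh <- kh[which.max(abs(kh$contrast)), ]
  # same physical location within 1 px, sigma halved within 10%
  expect_lt(abs(bf$x - 2 * bh$x), 1)
  expect_lt(abs(bf$y - 2 * bh$y), 1)
  expect_lt(abs(bf$sigma / (2 * bh$sigma) - 1), 0.1)
})
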