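test_that("ratio filter keeps exactly the candidates below T_R", {
  m <- data.frame(p = 1:2, q = 1:2, d1 = c(0.3, 0.5), d2 = c(0.6, 0.5))
  out <- ratio_filter(m, T_R = 0.65)
  expect_equal(out$p, 1)          # R = 0.5 kept; R = 1 (ambiguous) rejected
  expect_equal(out$R, 0.5)
  # planted ratios straddling the threshold vs an enumeration oracle
  set.seed(10)
  d2 <- runif(20, 0.5, 1)
  R <- runif(20, 0.3, 1)
  m <- data.frame(p = 1:20, q = 1:20, d1 = R * d2, d2 = d2)
  out <- ratio_filter(m, T_R = 0.65)
  expect_equal(nrow(out), sum(R < 0.65))
  expect_setequal(out$p, which(R < 0.65))
  # empty input, degenerate d2
  expect_equal(nrow(ratio_filter(m[0, ])), 0)
  expect_warning(z <- ratio_filter(data.frame(p = 1, q = 1, d1 = 0, d2 = 0)),
                 "duplicate")
  expect_equal(nrow(z), 0)
})

test_that("ratio filter is monotone in the threshold", {
  set.seed(11)
  m <- data.frame(p = 1:50, q = 1:50, d1 = runif(50), d2 = runif(50, 0.5, 1.5))
  prev <- integer(0)
  for (T_R in c(0.3, 0.5, 0.65, 0.8, 1.0)) {
    cur <- ratio_filter(m, T_R)$p
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("cross-validation is the bidirectional intersection", {
  A <- data.frame(p = c(1, 2), q = c(7, 9))
  B <- data.frame(p = 7, q = 1)
  C <- cross_validate(A, B)
  expect_equal(nrow(C), 1)
  expect_equal(c(C$p, C$q), c(1, 7))
  expect_equal(nrow(cross_validate(A[0, ], B)), 0)
  # random sets vs a double-loop enumeration oracle
  set.seed(12)
  A <- unique(data.frame(p = sample(50, 40, TRUE), q = sample(50, 40, TRUE)))
  B <- unique(data.frame(p = sample(50, 40, TRUE), q = sample(50, 40, TRUE)))
  C <- cross_validate(A, B)
  oracle <- logical(nrow(A))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      if (A$p[i] == B$q[j] && A$q[i] == B$p[j]) oracle[i] <- TRUE
  expect_equal(nrow(C), sum(oracle))
  expect_equal(C$p, A$p[oracle])  # order follows A
  expect_true(nrow(C) <= min(nrow(A), nrow(B)) || nrow(C) <= nrow(A))
})

test_that("RANSAC sampling count follows the closed form", {
  expect_equal(ransac_iterations(0.99, 1.0, 4), 1)
  # ceil(log 0.01 / log(1 - 0.5^4)) = 72
  expect_equal(ransac_iterations(0.99, 0.5, 4), 72)
  expect_equal(ransac_iterations(0.99, 0.5, 4),
               ceiling(log(1 - 0.99) / log(1 - 0.5^4)))
  # non-increasing in the inlier fraction
  N <- vapply(seq(0.1, 1, by = 0.05), function(w)
    as.numeric(ransac_iterations(0.99, w, 4)), numeric(1))
  expect_true(all(diff(N) <= 0))
})

test_that("inlier threshold is the chi-squared quantile times sigma^2", {
  expect_equal(inlier_threshold(0.01, 1), 9.210, tolerance = 1e-4)
  expect_equal(inlier_threshold(0.05, 1), 5.991, tolerance = 1e-4)
  expect_equal(inlier_threshold(0.01, 2), 4 * inlier_threshold(0.01, 1))
})

test_that("noiseless RANSAC recovers the exact transform and all inliers", {
  set.seed(13)
  H <- random_homography()
  x1 <- runif(30, 0, 200); y1 <- runif(30, 0, 200)
  mp <- apply_homography(H, cbind(x1, y1))
  pairs <- data.frame(x1 = x1, y1 = y1, x2 = mp[, 1], y2 = mp[, 2])
  rr <- ransac_homography(pairs, ransac_config(seed = 1))
  expect_true(rr$ok)
  expect_equal(rr$n_inliers, 30)
  expect_lt(max_corner_error(rr$H, H, c(200, 200)), 1e-6)
  # with zero outliers the refit equals the direct least-squares fit
  expect_equal(rr$H, solve_dlt(pairs), tolerance = 1e-9)
})

test_that("RANSAC separates planted inliers from uniform outliers", {
  inl_found <- out_admitted <- numeric(20)
  for (s in 1:20) {
    gm <- generate_matches(planted_match_spec(
      n_inliers = 100, n_outliers = 100, noise_sigma = 1,
      confusion_fraction = 0, seed = s))
    rr <- ransac_homography(gm$pairs, ransac_config(seed = s))
    inl_found[s] <- sum(rr$inlier_mask & gm$pairs$inlier)
    out_admitted[s] <- sum(rr$inlier_mask & !gm$pairs$inlier)
  }
  expect_gte(median(inl_found), 95)
  expect_lte(median(out_admitted), 5)
})

test_that("RANSAC decisions are stable across sampler seeds", {
  gm <- generate_matches(planted_match_spec(seed = 99))
  r1 <- ransac_homography(gm$pairs, ransac_config(seed = 1))
  r2 <- ransac_homography(gm$pairs, ransac_config(seed = 2))
  expect_equal(r1$ok, r2$ok)
  expect_lte(abs(r1$n_inliers - r2$n_inliers), 3)
})

test_that("RANSAC refuses fewer than 4 pairs and flags consensus failure", {
  expect_error(ransac_homography(data.frame(x1 = 1:3, y1 = 1:3,
                                            x2 = 1:3, y2 = 1:3)),
               "insufficient")
})

test_that("binomial verification implements the linear acceptance rule", {
  expect_false(verify_image_match(0, 0)$accepted)
  # n_f = 100: accepted iff n_i > 8 + 0.3*100 = 38, i.e. n_i >= 39
  acc <- vapply(0:100, function(ni) verify_image_match(100, ni)$accepted,
                logical(1))
  expect_equal(min(which(acc)) - 1, 39)
  expect_true(all(diff(acc) >= 0))  # monotone in n_i
  # posterior diagnostic behaves sensibly
  expect_gt(verify_image_match(100, 80)$posterior, 0.999)
  expect_lt(verify_image_match(100, 10)$posterior, 0.5)
})

test_that("purification never invents pairs and C is within A", {
  gm <- generate_matches(planted_match_spec(seed = 21))
  fw <- match_descriptors(gm$desc1, gm$desc2, method = "brute")
  bw <- match_descriptors(gm$desc2, gm$desc1, method = "brute")
  pur <- purify_matches(fw, bw, cbind(gm$pairs$x1, gm$pairs$y1),
                        cbind(gm$pairs$x2, gm$pairs$y2))
  expect_true(all(paste(pur$C$p, pur$C$q) %in% paste(pur$A$p, pur$A$q)))
  expect_lte(pur$m3, min(pur$m1, pur$m2))
  expect_lte(pur$ransac$n_inliers, pur$m3)
})

test_that("cascade precision ordering holds on planted sets", {
  tab <- benchmark_purification(seeds = 1:8)
  s <- attr(tab, "summary")
  expect_lt(s[["prec_before"]], s[["prec_ransac"]])
  expect_lt(s[["prec_ransac"]], s[["prec_improved"]])
  expect_gte(s[["prec_improved"]], 0.95)
})
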