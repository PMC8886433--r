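# Two-stage purification of tentative correspondences: the bidirectional
# K-nearest-neighbour ratio screen, then RANSAC with an adaptive sampling
# count, a chi-squared inlier threshold, and the binomial image-match
# verification.  This is the pipeline's core.

#' Nearest/second-nearest distance-ratio screen
#'
#' Keeps exactly the candidates whose ratio `R = d1/d2` is strictly below
#' `T_R`; an ambiguous match (nearest almost as far as the runner-up) is
#' rejected.  Candidates with `d2 <= 0` (duplicate descriptors) are
#' rejected with a warning.
#'
#' @param matches data frame with columns `d1`, `d2` (from
#'   [match_descriptors()]).
#' @param T_R ratio threshold (default 0.65, the operating point at
#'   which accuracy and match yield balance on endoscopic frames).
#' @return the surviving rows, with an added `R` column.
#' @export
ratio_filter <- function(matches, T_R = 0.65) {
  if (!nrow(matches)) { matches$R <- numeric(0); return(matches) }
  bad <- matches$d2 <= 0
  if (any(bad)) {
    warning(sum(bad), " candidate(s) with zero second-nearest distance ",
            "(duplicate descriptors) rejected")
    matches <- matches[!bad, , drop = FALSE]
  }
  matches$R <- matches$d1 / matches$d2
  out <- matches[matches$R < T_R, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bidirectional (cross-check) validation
#'
#' Keeps the pairs `(p, q)` of the forward set `A` whose reversed pair
#' `(q, p)` occurs in the backward set `B`; output order follows `A`.
#'
#' @param A forward matches (image1 -> image2), data frame with columns
#'   `p`, `q`.
#' @param B backward matches (image2 -> image1), columns `p` (image2
#'   index), `q` (image1 index).
#' @return the surviving rows of `A` (the set `C`).
#' @export
cross_validate <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(A[0, , drop = FALSE])
  keep <- paste(A$p, A$q) %in% paste(B$q, B$p)
  out <- A[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Required RANSAC sampling count
#'
#' Number of minimal samples `N` needed so that, with probability
#' `p_success`, at least one sample of `sample_size` pairs is all
#' inliers: `N = ceil(log(1 - p_success) / log(1 - w^m))` with `w` the
#' inlier fraction and `m` the sample size.
#'
#' @param p_success target confidence (default 0.99).
#' @param inlier_fraction fraction of inliers `w = 1 - epsilon` in
#'   `(0, 1]`.
#' @param sample_size minimal sample size `m` (4 pairs for a homography).
#' @return integer `N >= 1` (`Inf` if a success is essentially
#'   impossible).
#' @export
ransac_iterations <- function(p_success = 0.99, inlier_fraction,
                              sample_size = 4L) {
  stopifnot(p_success > 0, p_success < 1,
            inlier_fraction > 0, inlier_fraction <= 1)
  if (inlier_fraction == 1) return(1L)
  wm <- inlier_fraction^sample_size
  if (wm <= .Machine$double.eps) return(Inf)
  max(1, ceiling(log(1 - p_success) / log(1 - wm)))
}

#' Chi-squared inlier distance threshold
#'
#' If correspondence localization errors are zero-mean Gaussian with std
#' `sigma_noise` per coordinate, the squared transfer distance of a true
#' inlier is `sigma^2 * chi^2` with 2 degrees of freedom; the threshold
#' `t^2` at significance `m` is the `1 - m` quantile scaled by
#' `sigma_noise^2`.  Defaults give `t^2 = 9.21` at `sigma = 1`.
#'
#' @param significance false-rejection rate for true inliers (default
#'   0.01, i.e. 0.99 confidence).
#' @param sigma_noise assumed localization std in px (default 1).
#' @return squared distance threshold `t^2`.
#' @export
inlier_threshold <- function(significance = 0.01, sigma_noise = 1) {
  stopifnot(significance > 0, significance < 1, sigma_noise > 0)
  qchisq(1 - significance, df = 2) * sigma_noise^2
}

#' RANSAC configuration
#'
#' @param p_success target confidence that some sample is outlier-free
#'   (default 0.99).
#' @param significance inlier-threshold significance (default 0.01).
#' @param sigma_noise assumed localization std in px (default 1).
#' @param max_iters hard iteration cap (default 2000).
#' @param stall stop after this many iterations without an improved
#'   consensus (default 200), the "inlier count no longer increases"
#'   stopping note made concrete.
#' @param seed RNG seed for the sampler; `NULL` uses (and advances) the
#'   caller's RNG stream.
#' @return list of class `"ransac_config"`.
#' @export
ransac_config <- function(p_success = 0.99, significance = 0.01,
                          sigma_noise = 1, max_iters = 2000L, stall = 200L,
                          seed = 0L) {
  stopifnot(p_success > 0, p_success < 1, sigma_noise > 0)
  structure(list(p_success = p_success, significance = significance,
                 sigma_noise = sigma_noise, max_iters = max_iters,
                 stall = stall, seed = seed),
            class = "ransac_config")
}

# twice the signed triangle area for each triple of a 4-point sample
degenerate_sample <- function(x, y) {
  diag2 <- (max(x) - min(x))^2 + (max(y) - min(y))^2
  if (diag2 <= 0) return(TRUE)
  combs <- utils::combn(4L, 3L)
  for (j in seq_len(ncol(combs))) {
    i <- combs[, j]
    area2 <- abs((x[i[2]] - x[i[1]]) * (y[i[3]] - y[i[1]]) -
                 (x[i[3]] - x[i[1]]) * (y[i[2]] - y[i[1]]))
    if (area2 < 1e-6 * diag2) return(TRUE)
  }
  FALSE
}

#' Robust homography estimation by adaptive RANSAC
#'
#' Repeats: draw 4 correspondences (redrawing collinear or degenerate
#' samples), solve the exact homography, count inliers as pairs with
#' squared transfer error below [inlier_threshold()].  The best consensus
#' count `X` is tracked (the MAX update rule); after every improvement
#' the outlier fraction is re-estimated as `1 - X/n` and the required
#' iteration count recomputed via [ransac_iterations()].  The search
#' stops at that adaptive count, at `max_iters`, or after `stall`
#' iterations without improvement, and the model is refit on the maximal
#' inlier set by least squares ([solve_dlt()]), with the inlier mask
#' recomputed under the refit model.
#'
#' @param pairs data frame with columns `x1`, `y1`, `x2`, `y2` (and
#'   optionally others, preserved in the result); at least 4 rows.
#' @param config a [ransac_config()].
#' @return list of class `"ransac_result"`: `H` (or `NULL` on failure),
#'   `inlier_mask`, `n_inliers`, `X` (best consensus during search),
#'   `iterations`, `t2`, `sample_size = 4`, `ok`.
#' @export
ransac_homography <- function(pairs, config = ransac_config()) {
  pairs <- as.data.frame(pairs)
  n <- nrow(pairs)
  if (n < 4) stop("insufficient correspondences: RANSAC needs at least 4 pairs")
  t2 <- inlier_threshold(config$significance, config$sigma_noise)
  run <- function() {
    best_X <- 0L; best_mask <- NULL
    needed <- Inf; iter <- 0L; since_improve <- 0L
    while (iter < min(needed, config$max_iters) &&
           since_improve < config$stall) {
      iter <- iter + 1L
      s <- NULL
      for (try in 1:50) {
        cand <- sample.int(n, 4L)
        if (!degenerate_sample(pairs$x1[cand], pairs$y1[cand]) &&
            !degenerate_sample(pairs$x2[cand], pairs$y2[cand])) { s <- cand; break }
      }
      if (is.null(s)) break  # essentially all samples degenerate
      H <- tryCatch(solve_dlt(pairs[s, ], normalize = TRUE),
                    error = function(e) NULL)
      if (is.null(H)) next
      d2 <- tryCatch(backprojection_error(H, pairs)$per_pair,
                     error = function(e) NULL)
      if (is.null(d2)) next
      mask <- d2 < t2
      X <- sum(mask)
      if (X > best_X) {
        best_X <- X; best_mask <- mask; since_improve <- 0L
        needed <- ransac_iterations(config$p_success, X / n, 4L)
      } else since_improve <- since_improve + 1L
    }
    list(best_X = best_X, best_mask = best_mask, iterations = iter)
  }
  st <- if (is.null(config$seed)) run() else with_seed(config$seed, run())
  if (st$best_X < 4L) {
    return(structure(list(H = NULL, inlier_mask = rep(FALSE, n),
                          n_inliers = 0L, X = st$best_X,
                          iterations = st$iterations, t2 = t2,
                          sample_size = 4L, ok = FALSE, pairs = pairs),
                     class = "ransac_result"))
  }
  # refit on the consensus set, iterating until the inlier set is a
  # fixed point (removes dependence on which minimal sample won)
  mask <- st$best_mask
  H <- NULL
  for (it in 1:10) {
    H <- solve_dlt(pairs[mask, , drop = FALSE], normalize = TRUE)
    new_mask <- backprojection_error(H, pairs)$per_pair < t2
    if (sum(new_mask) >= 4L && !identical(new_mask, mask)) mask <- new_mask
    else break
  }
  structure(list(H = H, inlier_mask = mask, n_inliers = sum(mask),
                 X = st$best_X, iterations = st$iterations, t2 = t2,
                 sample_size = 4L, ok = TRUE, pairs = pairs),
            class = "ransac_result")
}

#' @export
print.ransac_result <- function(x, ...) {
  if (x$ok)
    cat("RANSAC: ", x$n_inliers, "/", nrow(x$pairs), " inliers (t2 = ",
        signif(x$t2, 4), ", ", x$iterations, " iterations)\n", sep = "")
  else
    cat("RANSAC failed: no model with >= 4 inliers\n")
  invisible(x)
}

#' Binomial verification parameters
#'
#' @param alpha_v,beta_v coefficients of the linear acceptance rule
#'   `n_i > alpha_v + beta_v * n_f` (defaults 8.0 and 0.3).
#' @param p1,p0 inlier probability of a tentative match when the images
#'   do / do not truly overlap (diagnostic posterior only).
#' @param prior prior probability that a random image pair truly matches.
#' @param p_min posterior needed to declare a match (diagnostic only).
#' @return list of class `"verification_params"`.
#' @export
verification_params <- function(alpha_v = 8.0, beta_v = 0.3,
                                p1 = 0.6, p0 = 0.1,
                                prior = 1e-6, p_min = 0.999) {
  stopifnot(p0 > 0, p1 > p0, p1 < 1, prior > 0, prior < 1)
  structure(list(alpha_v = alpha_v, beta_v = beta_v, p1 = p1, p0 = p0,
                 prior = prior, p_min = p_min),
            class = "verification_params")
}

#' Verify an image match from its inlier count
#'
#' The inlier count among `n_f` tentative matches is binomial with
#' success probability `p1` (true match) or `p0` (false match); the
#' posterior odds reduce, for fixed parameters, to the linear rule
#' `accept iff n_i > alpha_v + beta_v * n_f`.  The Bayesian posterior is
#' also computed from the two binomial likelihoods and the prior, as a
#' diagnostic.
#'
#' @param n_f number of tentative matches entering RANSAC.
#' @param n_i inlier count, `0 <= n_i <= n_f`.
#' @param params a [verification_params()].
#' @return list of class `"verification_result"`: `n_f`, `n_i`,
#'   `accepted`, `posterior`.
#' @export
verify_image_match <- function(n_f, n_i, params = verification_params()) {
  stopifnot(n_i >= 0, n_i <= max(n_f, 0))
  accepted <- n_i > params$alpha_v + params$beta_v * n_f
  posterior <- if (n_f > 0) {
    l1 <- dbinom(n_i, n_f, params$p1, log = TRUE)
    l0 <- dbinom(n_i, n_f, params$p0, log = TRUE)
    1 / (1 + exp(l0 - l1 + log1p(-params$prior) - log(params$prior)))
  } else params$prior
  structure(list(n_f = n_f, n_i = n_i, accepted = accepted,
                 posterior = posterior),
            class = "verification_result")
}

#' @export
print.verification_result <- function(x, ...) {
  cat("image-match verification: n_i = ", x$n_i, ", n_f = ", x$n_f,
      " -> ", if (x$accepted) "ACCEPTED" else "REJECTED",
      " (posterior ", signif(x$posterior, 4), ")\n", sep = "")
  invisible(x)
}

#' Full two-stage purification cascade
#'
#' Runs the ratio screen in both directions, intersects the two screened
#' sets (bidirectional cross-check), estimates the homography over the
#' intersection by adaptive RANSAC, and verifies the image match from the
#' inlier count.
#'
#' @param forward tentative matches image1 -> image2 (`p`, `q`, `d1`,
#'   `d2`).
#' @param backward tentative matches image2 -> image1.
#' @param coords1,coords2 `n x 2` matrices of keypoint `(x, y)`
#'   coordinates indexed by `p` and `q` respectively.
#' @param T_R ratio threshold (default 0.65).
#' @param rconfig a [ransac_config()].
#' @param vparams a [verification_params()].
#' @return list: sets `A`, `B`, `C` (with coordinates attached to `C`),
#'   counts `m1`, `m2`, `m3`, the `ransac` result, the `verification`
#'   result, and `inliers` (rows of `C` in the final consensus).
#' @export
purify_matches <- function(forward, backward, coords1, coords2, T_R = 0.65,
                           rconfig = ransac_config(),
                           vparams = verification_params()) {
  A <- ratio_filter(forward, T_R)
  B <- ratio_filter(backward, T_R)
  C <- cross_validate(A, B)
  if (nrow(C)) {
    C$x1 <- coords1[C$p, 1]; C$y1 <- coords1[C$p, 2]
    C$x2 <- coords2[C$q, 1]; C$y2 <- coords2[C$q, 2]
  } else {
    C$x1 <- C$y1 <- C$x2 <- C$y2 <- numeric(0)
  }
  rr <- if (nrow(C) >= 4) ransac_homography(C, rconfig) else
    structure(list(H = NULL, inlier_mask = rep(FALSE, nrow(C)),
                   n_inliers = 0L, X = 0L, iterations = 0L,
                   t2 = inlier_threshold(rconfig$significance,
                                         rconfig$sigma_noise),
                   sample_size = 4L, ok = FALSE, pairs = C),
              class = "ransac_result")
  ver <- verify_image_match(nrow(C), rr$n_inliers, vparams)
  list(A = A, B = B, C = C,
       m1 = nrow(A), m2 = nrow(B), m3 = nrow(C),
       ransac = rr, verification = ver,
       inliers = C[rr$inlier_mask, , drop = FALSE])
}
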