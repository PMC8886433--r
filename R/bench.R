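# Three-column purification benchmark on planted correspondence sets:
# raw tentative matches, RANSAC alone, and the full
# ratio + cross-check + RANSAC cascade, scored against the planted
# ground truth.

#' Benchmark the purification cascade on one planted set
#'
#' Generates a planted correspondence set, matches the planted
#' descriptors for real (exact 2-NN both directions), and scores three
#' match sets against the ground-truth labels: the raw tentative matches
#' ("before"), RANSAC applied directly to the tentative matches
#' ("ransac_only"), and the full cascade ("improved").  A surviving pair
#' `(p, q)` counts as correct iff `q` is `p`'s planted partner and the
#' pair was planted as an inlier.
#'
#' @param spec a [planted_match_spec()].
#' @param rconfig a [ransac_config()]; its seed also drives the sampler.
#' @param T_R ratio threshold (default 0.65).
#' @return one-row data frame: survivor counts and precisions of the
#'   three stages (`n_before`, `prec_before`, `n_ransac`, `prec_ransac`,
#'   `n_improved`, `prec_improved`).
#' @export
purification_trial <- function(spec, rconfig = ransac_config(seed = spec$seed),
                               T_R = 0.65) {
  gm <- generate_matches(spec)
  n <- nrow(gm$pairs)
  coords1 <- cbind(gm$pairs$x1, gm$pairs$y1)
  coords2 <- cbind(gm$pairs$x2, gm$pairs$y2)
  correct <- function(p, q) gm$pairs$inlier[p] & (q == p)
  forward <- match_descriptors(gm$desc1, gm$desc2, method = "brute")
  backward <- match_descriptors(gm$desc2, gm$desc1, method = "brute")

  # before: every tentative nearest-neighbour match
  ok_before <- correct(forward$p, forward$q)

  # RANSAC only, applied to the raw tentative matches
  raw <- data.frame(p = forward$p, q = forward$q,
                    x1 = coords1[forward$p, 1], y1 = coords1[forward$p, 2],
                    x2 = coords2[forward$q, 1], y2 = coords2[forward$q, 2])
  rr <- ransac_homography(raw, rconfig)
  ok_ransac <- correct(raw$p[rr$inlier_mask], raw$q[rr$inlier_mask])

  # full cascade
  pur <- purify_matches(forward, backward, coords1, coords2, T_R = T_R,
                        rconfig = rconfig)
  ok_improved <- correct(pur$inliers$p, pur$inliers$q)

  prec <- function(ok) if (length(ok)) mean(ok) else NA_real_
  data.frame(n_before = nrow(forward), prec_before = prec(ok_before),
             n_ransac = sum(rr$inlier_mask), prec_ransac = prec(ok_ransac),
             n_improved = nrow(pur$inliers), prec_improved = prec(ok_improved))
}

#' Run the purification benchmark over many seeds
#'
#' @param seeds integer vector of seeds, one trial each.
#' @param spec_args named list of [planted_match_spec()] overrides
#'   (`seed` is supplied per trial).
#' @param T_R ratio threshold (default 0.65).
#' @return data frame with one row per seed plus a `"summary"` attribute
#'   of median counts/precisions across trials.
#' @export
benchmark_purification <- function(seeds = 1:20, spec_args = list(),
                                   T_R = 0.65) {
  rows <- lapply(seeds, function(s) {
    spec <- do.call(planted_match_spec, c(spec_args, list(seed = s)))
    cbind(seed = s, purification_trial(spec, T_R = T_R))
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- vapply(out[, -1], median, numeric(1), na.rm = TRUE)
  out
}
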