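# Orientation assignment and the 128-d gradient-histogram descriptor.
#
# Convention: y points down the image rows; gradients are the unit-spacing
# central differences dx = L(x+1,y) - L(x-1,y), dy = L(x,y+1) - L(x,y-1),
# and theta = atan2(dy, dx) mapped to [0, 360) degrees.  atan2 fixes the
# quadrant that the bare arctan ratio formula leaves open.

#' Per-pixel gradient magnitude and direction of a blurred layer
#'
#' @param layer numeric matrix (a Gaussian scale-space layer).
#' @return list of two matrices, `mag` and `theta` (degrees in
#'   `[0, 360)`); the 1-px border, where central differences are
#'   unavailable, is zero in both.
#' @export
gradient_field <- function(layer) {
  h <- nrow(layer); w <- ncol(layer)
  mag <- theta <- matrix(0, h, w)
  if (h >= 3 && w >= 3) {
    ri <- 2:(h - 1); ci <- 2:(w - 1)
    dx <- layer[ri, ci + 1] - layer[ri, ci - 1]
    dy <- layer[ri + 1, ci] - layer[ri - 1, ci]
    mag[ri, ci] <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx) * 180 / pi
    theta[ri, ci] <- th %% 360
  }
  list(mag = mag, theta = theta)
}

# Gaussian layer on which a keypoint is described: same octave-relative
# scale as its DoG layer.  Returns the matrix plus the keypoint's
# octave-local coordinates and scale.
kp_layer <- function(kp, ss) {
  oc <- ss$gaussian[[kp$octave]]
  sc <- 2^(kp$octave - 1) * ss$scale0
  list(layer = oc$layers[[kp$layer]],
       x = kp$x / sc, y = kp$y / sc,
       sigma = ss$sigma0 * ss$k^(kp$layer - 1 + kp$off_s))
}

#' Orientation histogram of a keypoint neighbourhood
#'
#' 36-bin (10 degree) histogram of gradient directions in a circle of
#' radius `3 * 1.5 * sigma` around the keypoint, magnitudes weighted by a
#' Gaussian window of std `1.5 * sigma` (the circle radius is
#' standard; the weight width is the conventional companion choice).
#'
#' @param kp one keypoint row (from [detect_keypoints()]).
#' @param ss `"scale_space"` object.
#' @param n_bins histogram bins (default 36).
#' @return numeric vector of length `n_bins`; bin `b` covers
#'   `[(b-1)*360/n_bins, b*360/n_bins)` degrees.
#' @export
orientation_histogram <- function(kp, ss, n_bins = 36L) {
  kl <- kp_layer(kp, ss)
  cpp_orientation_hist(kl$layer, kl$x, kl$y,
                       sigma_w = 1.5 * kl$sigma,
                       radius = 3 * 1.5 * kl$sigma, nbins = n_bins)
}

#' Assign main (and auxiliary) orientations to keypoints
#'
#' The raw histogram is first smoothed with two passes of a circular
#' three-point box filter (peak positions would otherwise jitter between
#' adjacent bins under resampling).  One oriented keypoint is emitted for
#' the smoothed histogram's global peak and one more for every other
#' local maximum reaching at least 80% of the peak (the auxiliary-peak
#' rule).  Peak angles are refined by 3-point parabolic interpolation of
#' the circular histogram; ties go to the lower bin index.  Keypoints
#' with an all-zero histogram (flat patch) emit nothing.
#'
#' @param kps keypoint data frame.
#' @param ss `"scale_space"` object.
#' @param n_bins histogram bins (default 36).
#' @param peak_frac auxiliary-peak fraction (default 0.8).
#' @return oriented-keypoint data frame: the input columns plus `theta`
#'   (degrees in `[0, 360)`), possibly several rows per input keypoint.
#' @export
assign_orientations <- function(kps, ss, n_bins = 36L, peak_frac = 0.8) {
  out <- vector("list", nrow(kps))
  bin_width <- 360 / n_bins
  smooth_circ <- function(v) {
    n <- length(v)
    (v + v[c(n, seq_len(n - 1L))] + v[c(seq.int(2L, n), 1L)]) / 3
  }
  for (i in seq_len(nrow(kps))) {
    hist <- orientation_histogram(kps[i, ], ss, n_bins)
    hist <- smooth_circ(smooth_circ(hist))
    if (max(hist) <= 0) next
    peak <- max(hist)
    lo <- hist[c(n_bins, seq_len(n_bins - 1L))]  # circular left neighbour
    hi <- hist[c(seq.int(2L, n_bins), 1L)]       # circular right neighbour
    is_peak <- hist >= lo & hist >= hi & hist >= peak_frac * peak
    bins <- which(is_peak)
    # tie handling: the global max (lowest index on ties) always included
    bins <- union(which.max(hist), bins)
    thetas <- vapply(bins, function(b) {
      den <- lo[b] - 2 * hist[b] + hi[b]
      delta <- if (abs(den) > 1e-12) 0.5 * (lo[b] - hi[b]) / den else 0
      delta <- max(min(delta, 0.5), -0.5)
      ((b - 1 + 0.5 + delta) * bin_width) %% 360
    }, numeric(1))
    rows <- kps[rep(i, length(bins)), , drop = FALSE]
    rows$theta <- thetas
    out[[i]] <- rows
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    res <- kps[0, , drop = FALSE]
    res$theta <- numeric(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compute the 128-d descriptor of an oriented keypoint
#'
#' The neighbourhood is rotated by `-theta`, divided into a 4x4 grid of
#' spatial cells of side `3*sigma`, and each cell accumulates an 8-bin
#' (45 degree) histogram of gradient directions measured relative to
#' `theta`, with trilinear interpolation across the two spatial axes and
#' orientation and a Gaussian spatial weight of std `6*sigma` (half the
#' 12-sigma descriptor window).  The sampling radius carries a `sqrt(2)`
#' slack for the rotation.  The 4x4x8 = 128 vector is L2-normalized,
#' clamped at 0.2 per component (suppressing saturated gradient
#' directions from non-linear illumination), and renormalized.
#'
#' @param okp one oriented-keypoint row (from [assign_orientations()]).
#' @param ss `"scale_space"` object.
#' @param n_cells spatial cells per side (default 4).
#' @param n_ori orientation bins per cell (default 8).
#' @param cell_width_sigmas cell side in units of the keypoint scale
#'   (default 3).
#' @param clamp component ceiling before renormalization (default 0.2).
#' @return unit-norm numeric vector of length `n_cells^2 * n_ori` with
#'   attributes `"raw"` (pre-normalization histogram) and `"clamped"`
#'   (post-clamp, pre-renormalization vector), or `NULL` if the sampling
#'   window contains no usable pixels.
#' @export
compute_descriptor <- function(okp, ss, n_cells = 4L, n_ori = 8L,
                               cell_width_sigmas = 3, clamp = 0.2) {
  kl <- kp_layer(okp, ss)
  raw <- cpp_descriptor_raw(kl$layer, kl$x, kl$y,
                            hist_width = cell_width_sigmas * kl$sigma,
                            theta_rad = okp$theta * pi / 180,
                            d = n_cells, norient = n_ori,
                            win_sigma_cells = n_cells / 2)
  if (attr(raw, "n_used") == 0 || sum(raw) <= 0) return(NULL)
  v <- raw / sqrt(sum(raw^2))
  cl <- pmin(v, clamp)
  desc <- cl / sqrt(sum(cl^2))
  attr(desc, "raw") <- as.numeric(raw)
  attr(desc, "clamped") <- cl
  desc
}

#' Compute descriptors for a set of oriented keypoints
#'
#' @inheritParams compute_descriptor
#' @param okps oriented-keypoint data frame.
#' @return list with `descriptors` (matrix, one 128-d unit row per kept
#'   keypoint) and `keypoints` (the corresponding rows of `okps`);
#'   keypoints whose window held no usable pixels are dropped.
#' @export
compute_descriptors <- function(okps, ss, n_cells = 4L, n_ori = 8L,
                                cell_width_sigmas = 3, clamp = 0.2) {
  n <- nrow(okps)
  descs <- matrix(NA_real_, n, n_cells^2 * n_ori)
  ok <- logical(n)
  for (i in seq_len(n)) {
    d <- compute_descriptor(okps[i, ], ss, n_cells, n_ori,
                            cell_width_sigmas, clamp)
    if (!is.null(d)) { descs[i, ] <- d; ok[i] <- TRUE }
  }
  kps <- okps[ok, , drop = FALSE]
  rownames(kps) <- NULL
  list(descriptors = descs[ok, , drop = FALSE], keypoints = kps)
}
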