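# Gaussian/DoG scale space, extremum detection, sub-pixel refinement and
# the low-contrast / edge-response rejection tests.

#' Gaussian blur with reflected borders
#'
#' Separable Gaussian convolution, kernel truncated at `4*sigma`, borders
#' handled by mirror reflection (edge pixel repeated).  A normalized
#' kernel plus reflection keeps constant images exactly constant, which
#' makes the "DoG of a constant image is identically zero" invariant
#' exact rather than approximate.
#'
#' @param img numeric matrix.
#' @param sigma blur standard deviation in pixels; `sigma <= 0` returns
#'   the input unchanged.
#' @return blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 1e-12) return(img)
  r <- ceiling(4 * sigma)
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  blur_matrix(nrow(img), w, r) %*% img %*% t(blur_matrix(ncol(img), w, r))
}

# n x n banded convolution matrix with mirror-reflected indices
blur_matrix <- function(n, w, r) {
  M <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in -r:r) {
    j <- reflect_index(i + o, n)
    idx <- cbind(i, j)
    M[idx] <- M[idx] + w[o + r + 1]
  }
  M
}

# mirror reflection with the edge pixel repeated: 0 -> 1, -1 -> 2, n+1 -> n
reflect_index <- function(i, n) {
  repeat {
    low <- i < 1L
    i[low] <- 1L - i[low]
    high <- i > n
    i[high] <- 2L * n + 1L - i[high]
    if (!any(i < 1L | i > n)) return(i)
  }
}

#' Maximum feasible octave count for an image
#'
#' Octaves halve the image; each needs enough interior samples for the
#' 3x3x3 extremum test, so the coarsest octave must keep its smaller
#' dimension at least 8 px.
#'
#' @param img matrix, or `c(h, w)`.
#' @return integer >= 1.
#' @export
max_octaves <- function(img) {
  d <- if (is.matrix(img)) dim(img) else img
  max(1L, floor(log2(min(d) / 8)) + 1L)
}

#' Build the Gaussian and difference-of-Gaussians scale space
#'
#' Stacks `intervals + 3` Gaussian layers per octave at scales
#' `sigma0 * k^(j-1)` (octave-relative pixels), downsampling by 2 between
#' octaves, and forms the DoG stack as pairwise differences of adjacent
#' layers, `D_j = L_{j+1} - L_j`.  The input is assumed to carry
#' `assumed_blur` of smoothing already and is brought up to `sigma0`
#' before the first octave.
#'
#' The scale multiplier `k` defaults to `2^(1/intervals)`, the value
#' consistent with the small-`(k-1)` Laplacian approximation that makes
#' DoG a blob detector; `k = 2` is selectable for fidelity experiments
#' but collapses the per-octave scale sampling.
#'
#' @param img grayscale matrix in `[0, 1]`, at least 16x16.
#' @param sigma0 base scale in px (default 1.6).
#' @param intervals scales per octave doubling (default 3).
#' @param octaves number of octaves; default
#'   `floor(log2(min(h, w))) - 3`, clamped to the feasible range.
#' @param k scale multiplier between adjacent layers; default
#'   `2^(1/intervals)`.
#' @param assumed_blur smoothing already present in the input (default 0.5).
#' @param upsample if `TRUE`, bilinearly upsample the input 2x first
#'   (doubling the keypoint yield at the cost of 4x the work); off by
#'   default.
#' @return an object of class `"scale_space"`: a list with `gaussian` and
#'   `dog` (per octave: `layers`, a list of matrices, and `sigmas`, their
#'   octave-relative scales), plus `sigma0`, `k`, `intervals`,
#'   `n_octaves`, `scale0` (coordinate scale of octave 1: 0.5 when
#'   upsampled, else 1).
#' @export
build_scale_space <- function(img, sigma0 = 1.6, intervals = 3L, octaves = NULL,
                              k = NULL, assumed_blur = 0.5, upsample = FALSE) {
  check_gray_image(img)
  stopifnot(sigma0 > 0, intervals >= 1)
  if (is.null(k)) k <- 2^(1 / intervals)
  stopifnot(k > 1)
  scale0 <- 1
  if (upsample) {
    img <- upsample2x(img)
    assumed_blur <- assumed_blur * 2
    scale0 <- 0.5
  }
  feasible <- max_octaves(img)
  if (is.null(octaves)) {
    octaves <- min(feasible, max(1L, floor(log2(min(dim(img)))) - 3L))
  } else if (octaves > feasible) {
    stop("image of size ", nrow(img), "x", ncol(img), " supports at most ",
         feasible, " octave(s); ", octaves, " requested")
  }
  stopifnot(octaves >= 1)

  n_layers <- intervals + 3L
  sig_rel <- sigma0 * k^(seq_len(n_layers) - 1)
  # incremental blurs between adjacent layers within an octave
  inc <- sqrt(sig_rel[-1]^2 - sig_rel[-n_layers]^2)

  gauss <- vector("list", octaves)
  dog <- vector("list", octaves)
  base <- gaussian_blur(img, sqrt(max(sigma0^2 - assumed_blur^2, 1e-8)))
  for (o in seq_len(octaves)) {
    layers <- vector("list", n_layers)
    layers[[1]] <- base
    for (j in 2:n_layers) layers[[j]] <- gaussian_blur(layers[[j - 1]], inc[j - 1])
    dlayers <- vector("list", n_layers - 1L)
    for (j in seq_len(n_layers - 1L)) dlayers[[j]] <- layers[[j + 1]] - layers[[j]]
    gauss[[o]] <- list(layers = layers, sigmas = sig_rel)
    dog[[o]] <- list(layers = dlayers, sigmas = sig_rel[seq_len(n_layers - 1L)])
    if (o < octaves) {
      # layer `intervals + 1` has scale 2*sigma0: seed of the next octave
      seed_layer <- layers[[intervals + 1L]]
      base <- seed_layer[seq(1, nrow(seed_layer), by = 2),
                         seq(1, ncol(seed_layer), by = 2), drop = FALSE]
    }
  }
  structure(list(gaussian = gauss, dog = dog, sigma0 = sigma0, k = k,
                 intervals = as.integer(intervals),
                 n_octaves = as.integer(octaves), scale0 = scale0),
            class = "scale_space")
}

# bilinear 2x upsampling (output 2h x 2w, sample spacing halved)
upsample2x <- function(img) {
  h <- nrow(img); w <- ncol(img)
  yi <- (seq_len(2 * h) - 1) / 2
  xi <- (seq_len(2 * w) - 1) / 2
  bilinear_sample(img, rep(xi, each = 2 * h), rep(yi, times = 2 * w),
                  outside = 0)$values |>
    matrix(nrow = 2 * h, ncol = 2 * w)
}

#' @export
print.scale_space <- function(x, ...) {
  d1 <- dim(x$gaussian[[1]]$layers[[1]])
  cat("Gaussian/DoG scale space: ", x$n_octaves, " octave(s), ",
      length(x$gaussian[[1]]$layers), " layers each (intervals = ",
      x$intervals, ")\n", sep = "")
  cat("  base ", d1[1], "x", d1[2], ", sigma0 = ", x$sigma0,
      ", k = ", signif(x$k, 6), "\n", sep = "")
  invisible(x)
}

#' Detect local scale-space extrema in a DoG stack
#'
#' Returns the interior samples that are strictly greater than, or
#' strictly less than, all 26 neighbours in their 3x3x3 scale-space cube.
#' Border rows/columns and the first/last DoG layer of each octave are
#' excluded; plateaus (ties) are never reported.  Samples with
#' `|D| < 1e-12` are ignored: separable convolution leaves float noise
#' of order 1e-16 on an exactly constant image, ten orders of magnitude
#' below any usable contrast, and such samples must not masquerade as
#' extrema.
#'
#' @param ss a `"scale_space"` object (its `dog` component is used), or a
#'   bare DoG stack in the same per-octave `list(layers, sigmas)` layout.
#' @return data frame with 1-based columns `octave`, `layer`, `row`,
#'   `col` and the sample `value`; zero rows if there are no extrema.
#' @export
detect_extrema <- function(ss) {
  dog <- if (inherits(ss, "scale_space")) ss$dog else ss
  out <- vector("list", 0)
  for (o in seq_along(dog)) {
    layers <- dog[[o]]$layers
    nl <- length(layers)
    if (nl < 3L) stop("each octave needs at least 3 DoG layers")
    h <- nrow(layers[[1]]); w <- ncol(layers[[1]])
    if (h < 3L || w < 3L) next
    ri <- 2:(h - 1); ci <- 2:(w - 1)
    for (l in 2:(nl - 1)) {
      cur <- layers[[l]][ri, ci, drop = FALSE]
      nmax <- nmin <- NULL
      for (dl in -1:1) for (dr in -1:1) for (dc in -1:1) {
        if (dl == 0 && dr == 0 && dc == 0) next
        nb <- layers[[l + dl]][ri + dr, ci + dc, drop = FALSE]
        if (is.null(nmax)) { nmax <- nb; nmin <- nb }
        else { nmax <- pmax(nmax, nb); nmin <- pmin(nmin, nb) }
      }
      hit <- which(abs(cur) > 1e-12 & (cur > nmax | cur < nmin),
                   arr.ind = TRUE)
      if (nrow(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          octave = o, layer = l,
          row = hit[, 1] + 1L, col = hit[, 2] + 1L,
          value = cur[hit])
      }
    }
  }
  if (!length(out))
    return(data.frame(octave = integer(), layer = integer(),
                      row = integer(), col = integer(), value = numeric()))
  do.call(rbind, out)
}

# 3-D gradient and Hessian of D at integer sample (octave o, layer l, r, c),
# unit-spacing central differences; layer index is the third axis.
dog_derivs <- function(layers, l, r, c) {
  D <- layers[[l]]; Dp <- layers[[l + 1]]; Dm <- layers[[l - 1]]
  g <- c(
    (D[r, c + 1] - D[r, c - 1]) / 2,          # dD/dx
    (D[r + 1, c] - D[r - 1, c]) / 2,          # dD/dy
    (Dp[r, c] - Dm[r, c]) / 2                 # dD/ds
  )
  dxx <- D[r, c + 1] - 2 * D[r, c] + D[r, c - 1]
  dyy <- D[r + 1, c] - 2 * D[r, c] + D[r - 1, c]
  dss <- Dp[r, c] - 2 * D[r, c] + Dm[r, c]
  dxy <- (D[r + 1, c + 1] - D[r + 1, c - 1] - D[r - 1, c + 1] + D[r - 1, c - 1]) / 4
  dxs <- (Dp[r, c + 1] - Dp[r, c - 1] - Dm[r, c + 1] + Dm[r, c - 1]) / 4
  dys <- (Dp[r + 1, c] - Dp[r - 1, c] - Dm[r + 1, c] + Dm[r - 1, c]) / 4
  H <- matrix(c(dxx, dxy, dxs,
                dxy, dyy, dys,
                dxs, dys, dss), 3, 3)
  list(g = g, H = H, value = D[r, c])
}

#' Refine a candidate extremum to sub-pixel/sub-scale accuracy
#'
#' Fits the local 3-D quadratic (second-order Taylor expansion of the DoG
#' function) and solves for the stationary offset
#' `x_hat = -(d2D/dx2)^-1 (dD/dx)` by unit-spacing central differences.
#' If any offset component exceeds 0.5 the candidate is re-centred on the
#' neighbouring sample and the fit repeated, up to `max_iters` times.
#' Accepted keypoints must converge inside the stack and have interpolated
#' contrast `|D(x_hat)| >= contrast_threshold` (the "< 0.03 is too
#' unstable under noise" rule).
#'
#' @param cand one-row data frame or list with `octave`, `layer`, `row`,
#'   `col` (1-based, as produced by [detect_extrema()]).
#' @param ss `"scale_space"` object.
#' @param contrast_threshold minimum `|D(x_hat)|` (default 0.03).
#' @param max_iters re-centring attempts (default 5).
#' @return a one-row keypoint data frame (`x`, `y`, `sigma` in input-image
#'   pixels, `octave`, `layer`, `row`, `col`, `contrast`, `off_x`,
#'   `off_y`, `off_s`), or, if the candidate is rejected, a character
#'   scalar naming the reason (`"low contrast"`, `"singular Hessian"`,
#'   `"no convergence"`, `"wandered out of bounds"`, `"not interior"`).
#' @export
refine_keypoint <- function(cand, ss, contrast_threshold = 0.03, max_iters = 5L) {
  stopifnot(inherits(ss, "scale_space"))
  o <- cand$octave
  layers <- ss$dog[[o]]$layers
  nl <- length(layers)
  h <- nrow(layers[[1]]); w <- ncol(layers[[1]])
  l <- cand$layer; r <- cand$row; c <- cand$col
  reject <- function(reason) reason
  if (l < 2L || l > nl - 1L || r < 2L || r > h - 1L || c < 2L || c > w - 1L)
    return(reject("not interior"))
  off <- c(0, 0, 0)
  der <- NULL
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    der <- dog_derivs(layers, l, r, c)
    off <- tryCatch(-solve(der$H, der$g), error = function(e) NULL)
    if (is.null(off) || !all(is.finite(off)))
      return(reject("singular Hessian"))
    if (all(abs(off) <= 0.5)) { converged <- TRUE; break }
    step <- pmin(pmax(round(off), -1), 1)
    c <- c + step[1]; r <- r + step[2]; l <- l + step[3]
    if (l < 2L || l > nl - 1L || r < 2L || r > h - 1L || c < 2L || c > w - 1L)
      return(reject("wandered out of bounds"))
  }
  if (!converged) return(reject("no convergence"))
  contrast <- der$value + 0.5 * sum(der$g * off)
  if (abs(contrast) < contrast_threshold) return(reject("low contrast"))
  sc <- 2^(o - 1) * ss$scale0
  data.frame(
    x = (c - 1 + off[1]) * sc,
    y = (r - 1 + off[2]) * sc,
    sigma = ss$sigma0 * ss$k^(l - 1 + off[3]) * sc,
    octave = o, layer = l, row = r, col = c,
    contrast = contrast,
    off_x = off[1], off_y = off[2], off_s = off[3])
}

#' Refine many candidates
#'
#' Vectorized wrapper around [refine_keypoint()]; rejected candidates are
#' dropped and the rejection reasons tallied in the `"rejections"`
#' attribute.
#'
#' @inheritParams refine_keypoint
#' @param cands data frame from [detect_extrema()].
#' @return keypoint data frame (possibly zero rows).
#' @export
refine_keypoints <- function(cands, ss, contrast_threshold = 0.03, max_iters = 5L) {
  kept <- vector("list", nrow(cands))
  reasons <- character(0)
  for (i in seq_len(nrow(cands))) {
    kp <- refine_keypoint(cands[i, ], ss, contrast_threshold, max_iters)
    if (is.character(kp)) reasons <- c(reasons, kp) else kept[[i]] <- kp
  }
  kept <- kept[!vapply(kept, is.null, logical(1))]
  out <- if (length(kept)) do.call(rbind, kept) else
    data.frame(x = numeric(), y = numeric(), sigma = numeric(),
               octave = integer(), layer = integer(), row = integer(),
               col = integer(), contrast = numeric(), off_x = numeric(),
               off_y = numeric(), off_s = numeric())
  attr(out, "rejections") <- table(reasons)
  out
}

#' Principal-curvature (edge response) test
#'
#' Keypoints on edges have one large and one small principal curvature of
#' the DoG surface; such points localize poorly along the edge.  With the
#' 2x2 spatial Hessian `H` (central differences at the keypoint's integer
#' sample), a keypoint is kept iff `Det(H) > 0` and
#' `Tr(H)^2 / Det(H) < (gamma + 1)^2 / gamma`, i.e. its curvature ratio
#' is below `gamma`.  The bound is monotone in `gamma`; the default
#' `gamma = 10` gives threshold 12.1.
#'
#' @param kps keypoint data frame (needs `octave`, `layer`, `row`, `col`).
#' @param ss `"scale_space"` object.
#' @param gamma maximum admissible principal-curvature ratio (default 10).
#' @return logical vector, `TRUE` = keep.
#' @export
edge_response_filter <- function(kps, ss, gamma = 10) {
  stopifnot(gamma >= 1)
  thr <- (gamma + 1)^2 / gamma
  keep <- logical(nrow(kps))
  for (i in seq_len(nrow(kps))) {
    D <- ss$dog[[kps$octave[i]]]$layers[[kps$layer[i]]]
    r <- kps$row[i]; c <- kps$col[i]
    dxx <- D[r, c + 1] - 2 * D[r, c] + D[r, c - 1]
    dyy <- D[r + 1, c] - 2 * D[r, c] + D[r - 1, c]
    dxy <- (D[r + 1, c + 1] - D[r + 1, c - 1] - D[r - 1, c + 1] + D[r - 1, c - 1]) / 4
    det <- dxx * dyy - dxy^2
    tr <- dxx + dyy
    keep[i] <- det > 0 && (tr^2 / det) < thr
  }
  keep
}

#' Detect scale-space keypoints in an image
#'
#' The full detector: scale-space construction, 26-neighbour extremum
#' detection, Taylor refinement with the contrast cut, and the
#' principal-curvature edge test.
#'
#' @param img grayscale matrix in `[0, 1]` (use [to_gray()] first for RGB).
#' @param config a [pipeline_config()] list (only its detection fields are
#'   used).
#' @return keypoint data frame as from [refine_keypoints()], edge-filtered;
#'   the `"scale_space"` attribute carries the stack for later description.
#' @export
detect_keypoints <- function(img, config = pipeline_config()) {
  ss <- build_scale_space(img, sigma0 = config$sigma0,
                          intervals = config$intervals, k = config$k,
                          assumed_blur = config$assumed_blur,
                          upsample = config$upsample)
  cands <- detect_extrema(ss)
  kps <- refine_keypoints(cands, ss,
                          contrast_threshold = config$contrast_threshold)
  if (nrow(kps)) kps <- kps[edge_response_filter(kps, ss, config$gamma), , drop = FALSE]
  rownames(kps) <- NULL
  attr(kps, "scale_space") <- ss
  kps
}
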