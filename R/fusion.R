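# Warping onto a common canvas and gradual-in/gradual-out feathered
# blending of the overlap.
#
# Fusion-side convention: H maps image-2 coordinates into image 1's
# frame (the pipeline inverts its estimated image1 -> image2 transform
# before calling these).

#' Compute the mosaic canvas for a registered pair
#'
#' Transforms image 2's four corners by `H` and takes the bounding box of
#' image 1 together with those corners.  The returned offset is the
#' translation applied to image-1-frame coordinates to land on the
#' canvas.
#'
#' @param img1,img2 images (matrices or `h x w x 3` arrays).
#' @param H homography mapping image-2 coordinates to image 1's frame.
#' @return list of class `"canvas"`: `width`, `height`, `offset`
#'   (`c(ox, oy)`), and the mapped `corners2`.
#' @export
compute_canvas <- function(img1, img2, H) {
  d1 <- dim(img1)[1:2]; d2 <- dim(img2)[1:2]
  corners <- cbind(x = c(0, d2[2] - 1, 0, d2[2] - 1),
                   y = c(0, 0, d2[1] - 1, d2[1] - 1))
  mapped <- apply_homography(H, corners)
  if (!all(is.finite(mapped))) stop("image corner maps to infinity")
  xmin <- floor(min(0, mapped[, 1])); xmax <- ceiling(max(d1[2] - 1, mapped[, 1]))
  ymin <- floor(min(0, mapped[, 2])); ymax <- ceiling(max(d1[1] - 1, mapped[, 2]))
  structure(list(width = as.integer(xmax - xmin + 1),
                 height = as.integer(ymax - ymin + 1),
                 offset = c(-xmin, -ymin), corners2 = mapped),
            class = "canvas")
}

# bilinear sampling of matrix `img` at 0-based coordinates (x, y);
# returns values and an inside mask
bilinear_sample <- function(img, x, y, outside = 0) {
  h <- nrow(img); w <- ncol(img)
  inside <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  x0 <- pmin(pmax(floor(x), 0), w - 1); y0 <- pmin(pmax(floor(y), 0), h - 1)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- pmin(pmax(x - x0, 0), 1); fy <- pmin(pmax(y - y0, 0), 1)
  at <- function(r, c) img[cbind(r + 1, c + 1)]
  v <- (1 - fy) * ((1 - fx) * at(y0, x0) + fx * at(y0, x1)) +
       fy * ((1 - fx) * at(y1, x0) + fx * at(y1, x1))
  v[!inside] <- outside
  list(values = v, inside = inside)
}

#' Warp an image onto the canvas
#'
#' Backward mapping: every canvas pixel is sent through `H^-1` into
#' image 2 and bilinearly interpolated; the mask records which canvas
#' pixels hit the source footprint.
#'
#' @param img2 image to warp (matrix or `h x w x 3` array).
#' @param H homography mapping image-2 coordinates to image 1's frame.
#' @param canvas a [compute_canvas()] result.
#' @return list: `image` (canvas-sized), `mask` (logical matrix).
#' @export
warp_image <- function(img2, H, canvas) {
  Hi <- solve(H); Hi <- Hi / Hi[3, 3]
  W <- canvas$width; Hh <- canvas$height
  xs <- rep(seq_len(W) - 1 - canvas$offset[1], each = Hh)
  ys <- rep(seq_len(Hh) - 1 - canvas$offset[2], times = W)
  den <- Hi[3, 1] * xs + Hi[3, 2] * ys + Hi[3, 3]
  den[abs(den) < 1e-12] <- NA
  sx <- (Hi[1, 1] * xs + Hi[1, 2] * ys + Hi[1, 3]) / den
  sy <- (Hi[2, 1] * xs + Hi[2, 2] * ys + Hi[2, 3]) / den
  sx[is.na(sx)] <- -1e9; sy[is.na(sy)] <- -1e9
  if (is.matrix(img2)) {
    s <- bilinear_sample(img2, sx, sy)
    img <- matrix(s$values, Hh, W)
    mask <- matrix(s$inside, Hh, W)
  } else {
    ch <- lapply(1:3, function(k) {
      s <- bilinear_sample(img2[, , k], sx, sy)
      matrix(s$values, Hh, W)
    })
    img <- array(unlist(ch), dim = c(Hh, W, 3))
    mask <- matrix(bilinear_sample(img2[, , 1], sx, sy)$inside, Hh, W)
  }
  list(image = img, mask = mask)
}

#' Place an unwarped image on the canvas
#'
#' @param img1 reference image.
#' @param canvas a [compute_canvas()] result.
#' @return list: `image`, `mask`.
#' @export
place_on_canvas <- function(img1, canvas) {
  d <- dim(img1)
  rows <- seq_len(d[1]) + canvas$offset[2]
  cols <- seq_len(d[2]) + canvas$offset[1]
  mask <- matrix(FALSE, canvas$height, canvas$width)
  mask[rows, cols] <- TRUE
  if (is.matrix(img1)) {
    img <- matrix(0, canvas$height, canvas$width)
    img[rows, cols] <- img1
  } else {
    img <- array(0, dim = c(canvas$height, canvas$width, 3))
    img[rows, cols, ] <- img1
  }
  list(image = img, mask = mask)
}

# two-pass 3-4 chamfer distance to the complement of a logical mask
chamfer_distance <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  big <- 3 * (h + w)
  d <- matrix(0, h, w)
  d[mask] <- big
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (d[r, c] == 0) next
    v <- d[r, c]
    if (r > 1) { v <- min(v, d[r - 1, c] + 3); if (c > 1) v <- min(v, d[r - 1, c - 1] + 4); if (c < w) v <- min(v, d[r - 1, c + 1] + 4) }
    if (c > 1) v <- min(v, d[r, c - 1] + 3)
    d[r, c] <- v
  }
  for (r in rev(seq_len(h))) for (c in rev(seq_len(w))) {
    if (d[r, c] == 0) next
    v <- d[r, c]
    if (r < h) { v <- min(v, d[r + 1, c] + 3); if (c < w) v <- min(v, d[r + 1, c + 1] + 4); if (c > 1) v <- min(v, d[r + 1, c - 1] + 4) }
    if (c < w) v <- min(v, d[r, c + 1] + 3)
    d[r, c] <- v
  }
  d / 3
}

# per-line linear feathering weights for image 1 over the overlap
linear_weights <- function(mask1, mask2, overlap) {
  w1 <- matrix(NA_real_, nrow(overlap), ncol(overlap))
  # ramp along the dominant displacement axis of the two footprints
  c1 <- footprint_centroid(mask1); c2 <- footprint_centroid(mask2)
  disp <- c2 - c1
  horizontal <- abs(disp[1]) >= abs(disp[2])
  lines <- if (horizontal) seq_len(nrow(overlap)) else seq_len(ncol(overlap))
  for (i in lines) {
    ov <- if (horizontal) which(overlap[i, ]) else which(overlap[, i])
    if (!length(ov)) next
    s <- min(ov); e <- max(ov)
    width <- e - s
    ramp <- if (width == 0) 0.5 else (ov - s) / width
    d1 <- if ((if (horizontal) disp[1] else disp[2]) >= 0) 1 - ramp else ramp
    if (horizontal) w1[i, ov] <- d1 else w1[ov, i] <- d1
  }
  w1
}

footprint_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 2]), mean(idx[, 1]))  # (x, y)
}

#' Gradual-in/gradual-out weighted fusion
#'
#' Composites two canvas-aligned images: each image alone where only it
#' covers the canvas, and the convex combination `d1*I1 + d2*I2` in the
#' overlap, where the weight `d1` ramps linearly from 1 on image 1's
#' side of the overlap to 0 on image 2's side (per row or per column,
#' along the dominant displacement axis) and `d2 = 1 - d1`.  A
#' distance-transform weight (`d1 = dist1 / (dist1 + dist2)` from the two
#' footprint boundaries) is available for irregular overlaps.
#'
#' A variant of the fusion rule that circulates in the literature halves
#' the blended overlap term; that contradicts the constraint
#' `d1 + d2 = 1` (it would darken the seam), so the default omits the
#' halving.  Set `literal_overlap_halving = TRUE` to reproduce the
#' halved variant for comparison.
#'
#' @param im1 output of [place_on_canvas()] (list `image`, `mask`).
#' @param im2 output of [warp_image()] (list `image`, `mask`).
#' @param mode `"linear"` (default) or `"distance"`.
#' @param literal_overlap_halving divide the blended overlap by 2
#'   (default `FALSE`).
#' @return list of class `"mosaic"`: `image`, `weight1`, `weight2`
#'   (matrices, `NA` outside the overlap), `overlap` (logical matrix).
#' @export
blend_gradual <- function(im1, im2, mode = c("linear", "distance"),
                          literal_overlap_halving = FALSE) {
  mode <- match.arg(mode)
  mask1 <- im1$mask; mask2 <- im2$mask
  overlap <- mask1 & mask2
  if (!any(overlap))
    warning("empty overlap: images composited without blending ",
            "(registration may have failed verification)")
  w1 <- if (!any(overlap)) {
    matrix(NA_real_, nrow(mask1), ncol(mask1))
  } else if (mode == "linear") {
    linear_weights(mask1, mask2, overlap)
  } else {
    d1 <- chamfer_distance(mask1); d2 <- chamfer_distance(mask2)
    w <- matrix(NA_real_, nrow(mask1), ncol(mask1))
    w[overlap] <- d1[overlap] / (d1[overlap] + d2[overlap])
    w
  }
  blend_plane <- function(p1, p2) {
    out <- matrix(0, nrow(mask1), ncol(mask1))
    out[mask1 & !mask2] <- p1[mask1 & !mask2]
    out[mask2 & !mask1] <- p2[mask2 & !mask1]
    if (any(overlap)) {
      b <- w1[overlap] * p1[overlap] + (1 - w1[overlap]) * p2[overlap]
      if (literal_overlap_halving) b <- b / 2
      out[overlap] <- b
    }
    out
  }
  img <- if (is.matrix(im1$image)) blend_plane(im1$image, im2$image)
  else {
    ch <- lapply(1:3, function(k) blend_plane(im1$image[, , k], im2$image[, , k]))
    array(unlist(ch), dim = dim(im1$image))
  }
  w2 <- 1 - w1
  structure(list(image = img, weight1 = w1, weight2 = w2, overlap = overlap),
            class = "mosaic")
}

#' Build the mosaic of a registered pair
#'
#' Convenience wrapper: canvas, warp, placement and blending in one call.
#'
#' @param img1,img2 images.
#' @param H homography mapping image-2 coordinates into image 1's frame.
#' @param ... passed to [blend_gradual()].
#' @return a `"mosaic"` (see [blend_gradual()]) with the `canvas`
#'   attached.
#' @export
mosaic_pair <- function(img1, img2, H, ...) {
  canvas <- compute_canvas(img1, img2, H)
  im1 <- place_on_canvas(img1, canvas)
  im2 <- warp_image(img2, H, canvas)
  m <- blend_gradual(im1, im2, ...)
  m$canvas <- canvas
  m
}
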