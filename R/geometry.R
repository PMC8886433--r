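# Homography estimation by the direct linear transform and transfer /
# back-projection errors.  A homography is a plain 3x3 matrix with the
# bottom-right entry fixed to 1, so it has the 8 free parameters
# h11..h32.

#' Apply a homography to points
#'
#' Maps `(x, y)` to
#' `((h11 x + h12 y + h13) / w, (h21 x + h22 y + h23) / w)` with
#' `w = h31 x + h32 y + 1`.
#'
#' @param H 3x3 homography matrix, `H[3, 3] == 1`.
#' @param pts length-2 vector or an `n x 2` matrix of `(x, y)` points.
#' @return points of the same shape.
#' @export
apply_homography <- function(H, pts) {
  vec <- !is.matrix(pts)
  if (vec) pts <- matrix(pts, nrow = 1)
  stopifnot(ncol(pts) == 2)
  den <- H[3, 1] * pts[, 1] + H[3, 2] * pts[, 2] + H[3, 3]
  if (any(abs(den) < 1e-12))
    stop("point at infinity: projective denominator vanishes")
  out <- cbind((H[1, 1] * pts[, 1] + H[1, 2] * pts[, 2] + H[1, 3]) / den,
               (H[2, 1] * pts[, 1] + H[2, 2] * pts[, 2] + H[2, 3]) / den)
  if (vec) out[1, ] else out
}

# similarity that moves points to centroid 0, mean distance sqrt(2)
norm_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
}

# 2n x 8 DLT design matrix and right-hand side for X h = y
dlt_system <- function(x1, y1, x2, y2) {
  n <- length(x1)
  X <- matrix(0, 2 * n, 8)
  odd <- seq.int(1L, 2L * n, 2L)
  X[odd, 1] <- x1; X[odd, 2] <- y1; X[odd, 3] <- 1
  X[odd, 7] <- -x2 * x1; X[odd, 8] <- -x2 * y1
  X[odd + 1L, 4] <- x1; X[odd + 1L, 5] <- y1; X[odd + 1L, 6] <- 1
  X[odd + 1L, 7] <- -y2 * x1; X[odd + 1L, 8] <- -y2 * y1
  y <- numeric(2 * n)
  y[odd] <- x2; y[odd + 1L] <- y2
  list(X = X, y = y)
}

#' Estimate a homography by the direct linear transform
#'
#' Builds the `2n x 8` linear system in the parameters h11..h32 (one pair
#' of rows per correspondence) and solves it by QR least squares, which
#' minimizes `||X h - y||^2` and coincides with the normal-equation
#' solution `(X'X)^-1 X'y` whenever `X'X` is well conditioned.  With 4
#' non-collinear pairs the system is square and solved exactly.
#'
#' By default both point sets are first normalized to centroid 0 / mean
#' distance `sqrt(2)` (Hartley conditioning) and the result denormalized;
#' set `normalize = FALSE` to solve the raw system, which is numerically
#' fragile at image-scale coordinates but reproduces the plain
#' normal-equation path exactly.
#'
#' @param pairs data frame or matrix with columns `x1`, `y1`, `x2`, `y2`
#'   (source and target points); at least 4 rows, not all collinear.
#' @param normalize use Hartley conditioning (default `TRUE`).
#' @return 3x3 homography matrix mapping `(x1, y1)` to `(x2, y2)`,
#'   `H[3, 3] == 1`.
#' @export
solve_dlt <- function(pairs, normalize = TRUE) {
  pairs <- as.data.frame(pairs)
  n <- nrow(pairs)
  if (n < 4) stop("need at least 4 point pairs")
  x1 <- pairs$x1; y1 <- pairs$y1; x2 <- pairs$x2; y2 <- pairs$y2
  if (normalize) {
    T1 <- norm_transform(cbind(x1, y1))
    T2 <- norm_transform(cbind(x2, y2))
    p1 <- apply_homography(T1, cbind(x1, y1))
    p2 <- apply_homography(T2, cbind(x2, y2))
    sys <- dlt_system(p1[, 1], p1[, 2], p2[, 1], p2[, 2])
  } else {
    sys <- dlt_system(x1, y1, x2, y2)
  }
  qrX <- qr(sys$X)
  if (qrX$rank < 8)
    stop("degenerate configuration: DLT system has rank ", qrX$rank,
         " < 8 (collinear or coincident points)")
  h <- qr.coef(qrX, sys$y)
  H <- matrix(c(h[1:3], h[4:6], h[7:8], 1), 3, 3, byrow = TRUE)
  if (normalize) {
    H <- solve(T2) %*% H %*% T1
    if (abs(H[3, 3]) < 1e-12)
      stop("estimated transform has h33 ~ 0; the h33 = 1 parameterization fails")
    H <- H / H[3, 3]
  }
  H
}

#' Back-projection (transfer) error of a homography
#'
#' Per-pair squared distance between the observed target point and the
#' source point mapped through `H`, plus their sum `E`.
#'
#' @param H 3x3 homography.
#' @param pairs data frame with `x1`, `y1`, `x2`, `y2`.
#' @return list with `per_pair` (vector of squared distances `d_v^2`) and
#'   `total` (their sum `E`).
#' @export
backprojection_error <- function(H, pairs) {
  pairs <- as.data.frame(pairs)
  mapped <- apply_homography(H, cbind(pairs$x1, pairs$y1))
  d2 <- (pairs$x2 - mapped[, 1])^2 + (pairs$y2 - mapped[, 2])^2
  list(per_pair = d2, total = sum(d2))
}

#' Homographies for common special cases
#'
#' Convenience constructors used by the synthetic generator and tests.
#'
#' @param tx,ty translation in px.
#' @param angle rotation in degrees (counter-clockwise in the y-down
#'   image frame).
#' @param scale isotropic scale factor.
#' @param center length-2 rotation/scaling centre (default origin).
#' @return 3x3 homography matrix.
#' @export
translation_homography <- function(tx, ty) {
  matrix(c(1, 0, tx, 0, 1, ty, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' @rdname translation_homography
#' @export
similarity_homography <- function(angle = 0, scale = 1, tx = 0, ty = 0,
                                  center = c(0, 0)) {
  a <- angle * pi / 180
  R <- scale * matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
  t <- c(tx, ty) + center - R %*% center
  matrix(c(R[1, ], t[1], R[2, ], t[2], 0, 0, 1), 3, 3, byrow = TRUE)
}
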