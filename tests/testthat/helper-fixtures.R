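# Fixtures are built in code at test time; nothing is stored on disk.

# isolated Gaussian blob on a dark background
blob_image <- function(h = 64, w = 64, cx = (w - 1) / 2, cy = (h - 1) / 2,
                       s = 4, amp = 0.5, bg = 0.1) {
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  pmin(pmax(bg + amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)), 0), 1)
}

# textured test image (contrast-stretched multi-octave value noise)
texture_image <- function(seed = 1, h = 96, w = 96) {
  generate_pair(scene_spec(seed = seed, size = c(h, w), noise_sd = 0,
                           gain_jitter = 0, offset_jitter = 0),
                diag(3))$img1
}

# hand-built scale_space carrying a single-octave DoG stack, for the
# refinement and edge-response unit tests
fake_dog_ss <- function(layers, sigma0 = 1.6, k = 2^(1/3)) {
  structure(list(
    gaussian = NULL,
    dog = list(list(layers = layers,
                    sigmas = sigma0 * k^(seq_along(layers) - 1))),
    sigma0 = sigma0, k = k, intervals = length(layers) - 2L,
    n_octaves = 1L, scale0 = 1), class = "scale_space")
}

# separable quadratic DoG stack with analytic peak at
# (col-1 + ox, row-1 + oy, layer-1 + os) and peak value `peak`
quad_dog_stack <- function(n = 11, layers = 5, peak = 0.1,
                           center = c(6, 6, 3), offset = c(0, 0, 0),
                           curv = c(0.02, 0.03, 0.04)) {
  x0 <- center[1] + offset[1]; y0 <- center[2] + offset[2]
  l0 <- center[3] + offset[3]
  lapply(seq_len(layers), function(l) {
    outer(seq_len(n), seq_len(n), function(r, c)
      peak - curv[1] * (c - x0)^2 - curv[2] * (r - y0)^2 -
        curv[3] * (l - l0)^2)
  })
}

# hand-built scale_space around a single Gaussian layer, for descriptor
# unit tests; keypoint at 0-based (x, y) with scale sigma
fake_layer_ss <- function(L, sigma0 = 1.6) {
  structure(list(
    gaussian = list(list(layers = list(L, L, L),
                         sigmas = sigma0 * 2^((0:2) / 3))),
    dog = NULL, sigma0 = sigma0, k = 2^(1/3), intervals = 1L,
    n_octaves = 1L, scale0 = 1), class = "scale_space")
}

fake_kp <- function(x, y, sigma = 1.6, layer = 1L, theta = NULL) {
  kp <- data.frame(x = x, y = y, sigma = sigma, octave = 1L,
                   layer = layer, row = round(y) + 1L, col = round(x) + 1L,
                   contrast = 0.1, off_x = 0, off_y = 0,
                   off_s = log(sigma / (1.6 * 2^((layer - 1) / 3))) / log(2^(1/3)))
  if (!is.null(theta)) kp$theta <- theta
  kp
}

# rotate a matrix image 90 degrees clockwise (in the y-down display);
# 0-based point (x, y) maps to (h - 1 - y, x)
rot90cw <- function(img) t(img[nrow(img):1, , drop = FALSE])

# pad 2-d points up to dimension d for descriptor-search tests
pad_desc <- function(m, d = 128) {
  out <- matrix(0, nrow(m), d)
  out[, seq_len(ncol(m))] <- m
  out
}

max_corner_error <- function(H_est, H_true, size) {
  corners <- cbind(c(0, size[2] - 1, 0, size[2] - 1),
                   c(0, 0, size[1] - 1, size[1] - 1))
  max(sqrt(rowSums((apply_homography(H_est, corners) -
                    apply_homography(H_true, corners))^2)))
}

random_homography <- function() {
  H <- diag(3)
  H[1, 1] <- runif(1, 0.8, 1.2); H[2, 2] <- runif(1, 0.8, 1.2)
  H[1, 2] <- runif(1, -0.2, 0.2); H[2, 1] <- runif(1, -0.2, 0.2)
  H[1, 3] <- runif(1, -30, 30); H[2, 3] <- runif(1, -30, 30)
  H[3, 1] <- runif(1, -1e-3, 1e-3); H[3, 2] <- runif(1, -1e-3, 1e-3)
  H
}
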