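# The end-to-end pipeline: detect -> describe -> match -> ratio screen ->
# cross-check -> RANSAC -> binomial verification -> warp -> blend.

#' Pipeline configuration
#'
#' Every tunable of the stitching pipeline with its default.  Unknown
#' names are rejected.
#'
#' @param sigma0 base detection scale in px (1.6).
#' @param intervals scales per octave doubling (3).
#' @param k scale multiplier between adjacent layers; `NULL` =
#'   `2^(1/intervals)`.  `k = 2` is selectable for fidelity runs.
#' @param octaves octave count; `NULL` = automatic from the image size.
#' @param assumed_blur smoothing assumed in the input (0.5 px).
#' @param upsample 2x-upsample the input before detection (FALSE).
#' @param contrast_threshold minimum refined `|D(x_hat)|` (0.03).
#' @param gamma maximum principal-curvature ratio (10).
#' @param ratio nearest/second-nearest distance-ratio threshold `T_R`
#'   (0.65).
#' @param matcher `"bbf"` or `"brute"`.
#' @param bbf_budget BBF leaf budget (200).
#' @param p_success RANSAC confidence (0.99).
#' @param significance inlier-threshold significance (0.01).
#' @param sigma_noise assumed localization std in px (1.0).
#' @param max_iters,stall RANSAC iteration cap and stall window.
#' @param alpha_v,beta_v verification rule coefficients (8.0, 0.3).
#' @param p1,p0,prior,p_min verification diagnostics (see
#'   [verification_params()]).
#' @param seed RANSAC sampler seed (0).
#' @param blend_mode `"linear"` or `"distance"` feathering.
#' @param literal_overlap_halving halve the blended overlap term
#'   (FALSE; see [blend_gradual()]).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sigma0 = 1.6, intervals = 3L, k = NULL,
                            octaves = NULL, assumed_blur = 0.5,
                            upsample = FALSE, contrast_threshold = 0.03,
                            gamma = 10, ratio = 0.65,
                            matcher = c("bbf", "brute"), bbf_budget = 200,
                            p_success = 0.99, significance = 0.01,
                            sigma_noise = 1.0, max_iters = 2000L,
                            stall = 200L, alpha_v = 8.0, beta_v = 0.3,
                            p1 = 0.6, p0 = 0.1, prior = 1e-6,
                            p_min = 0.999, seed = 0L,
                            blend_mode = c("linear", "distance"),
                            literal_overlap_halving = FALSE) {
  matcher <- match.arg(matcher)
  blend_mode <- match.arg(blend_mode)
  stopifnot(sigma0 > 0, intervals >= 1, contrast_threshold >= 0, gamma >= 1,
            ratio > 0, ratio <= 1, bbf_budget >= 2,
            p_success > 0, p_success < 1, sigma_noise > 0)
  if (is.null(k)) k <- 2^(1 / intervals)
  structure(list(sigma0 = sigma0, intervals = as.integer(intervals), k = k,
                 octaves = octaves, assumed_blur = assumed_blur,
                 upsample = upsample,
                 contrast_threshold = contrast_threshold, gamma = gamma,
                 ratio = ratio, matcher = matcher, bbf_budget = bbf_budget,
                 p_success = p_success, significance = significance,
                 sigma_noise = sigma_noise, max_iters = max_iters,
                 stall = stall, alpha_v = alpha_v, beta_v = beta_v,
                 p1 = p1, p0 = p0, prior = prior, p_min = p_min,
                 seed = seed, blend_mode = blend_mode,
                 literal_overlap_halving = literal_overlap_halving),
            class = "pipeline_config")
}

#' Update a pipeline configuration from a named list
#'
#' Used by the configuration-file and CLI-flag plumbing; unknown keys
#' are an error.
#'
#' @param config a [pipeline_config()].
#' @param values named list of overrides.
#' @return updated configuration.
#' @export
update_config <- function(config, values) {
  if (!length(values)) return(config)
  unknown <- setdiff(names(values), names(config))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  args <- utils::modifyList(as.list(unclass(config)), values)
  do.call(pipeline_config, args[setdiff(names(args), character(0))])
}

#' Detect keypoints and compute their descriptors
#'
#' @param img grayscale or RGB image in `[0, 1]`.
#' @param config a [pipeline_config()].
#' @return list: `keypoints` (oriented-keypoint data frame),
#'   `descriptors` (matrix with one 128-d row per keypoint).
#' @export
detect_and_describe <- function(img, config = pipeline_config()) {
  gray <- to_gray(img)
  kps <- detect_keypoints(gray, config)
  ss <- attr(kps, "scale_space")
  if (!nrow(kps))
    return(list(keypoints = cbind(kps, theta = numeric(0)),
                descriptors = matrix(numeric(0), 0, 128)))
  okps <- assign_orientations(kps, ss)
  compute_descriptors(okps, ss)
}

#' Stitch two overlapping images
#'
#' Runs the full pipeline and, if the binomial verification accepts the
#' image match, fuses the pair into a mosaic.  The homography `H` maps
#' image-1 coordinates to image-2 coordinates; fusion warps image 2 into
#' image 1's frame through its inverse.
#'
#' @param img1,img2 images in `[0, 1]` (matrices or `h x w x 3` arrays);
#'   RGB inputs are matched on luminance and blended per channel.
#' @param config a [pipeline_config()].
#' @return list of class `"stitch_result"`:
#'   `mosaic` (a [blend_gradual()] result, or `NULL` if rejected), `H`,
#'   `accepted`, `report` (keypoint and match counts `n_kp1`, `n_kp2`,
#'   `m1`, `m2`, `m3`, `n_i`, `accepted`, `posterior`, back-projection
#'   error `E` over the final inliers, `corner_transfer` of image 2's
#'   corners), and the `purify` stage detail.
#' @export
stitch_images <- function(img1, img2, config = pipeline_config()) {
  f1 <- detect_and_describe(img1, config)
  f2 <- detect_and_describe(img2, config)
  n1 <- nrow(f1$keypoints); n2 <- nrow(f2$keypoints)
  forward <- match_descriptors(f1$descriptors, f2$descriptors,
                               method = config$matcher,
                               node_budget = config$bbf_budget)
  backward <- match_descriptors(f2$descriptors, f1$descriptors,
                                method = config$matcher,
                                node_budget = config$bbf_budget)
  pur <- purify_matches(
    forward, backward,
    coords1 = as.matrix(f1$keypoints[, c("x", "y")]),
    coords2 = as.matrix(f2$keypoints[, c("x", "y")]),
    T_R = config$ratio,
    rconfig = ransac_config(config$p_success, config$significance,
                            config$sigma_noise, config$max_iters,
                            config$stall, config$seed),
    vparams = verification_params(config$alpha_v, config$beta_v,
                                  config$p1, config$p0, config$prior,
                                  config$p_min))
  accepted <- pur$verification$accepted && pur$ransac$ok
  H <- pur$ransac$H
  E <- if (pur$ransac$ok && nrow(pur$inliers))
    backprojection_error(H, pur$inliers)$total else NA_real_
  mosaic <- NULL
  if (accepted) {
    Hi <- solve(H); Hi <- Hi / Hi[3, 3]
    mosaic <- mosaic_pair(img1, img2, Hi, mode = config$blend_mode,
                          literal_overlap_halving = config$literal_overlap_halving)
  }
  report <- list(n_kp1 = n1, n_kp2 = n2,
                 m1 = pur$m1, m2 = pur$m2, m3 = pur$m3,
                 n_f = pur$m3, n_i = pur$ransac$n_inliers,
                 iterations = pur$ransac$iterations,
                 accepted = accepted,
                 posterior = pur$verification$posterior, E = E)
  structure(list(mosaic = mosaic, H = H, accepted = accepted,
                 report = report, purify = pur,
                 features1 = f1, features2 = f2),
            class = "stitch_result")
}

#' @export
print.stitch_result <- function(x, ...) {
  r <- x$report
  cat("stitch: ", r$n_kp1, "/", r$n_kp2, " keypoints; m1 = ", r$m1,
      ", m2 = ", r$m2, ", m3 = ", r$m3, "; inliers n_i = ", r$n_i,
      " -> ", if (r$accepted) "ACCEPTED" else "REJECTED", "\n", sep = "")
  invisible(x)
}

#' Serialize matches as TSV
#'
#' Columns: `p_idx`, `q_idx`, `x1`, `y1`, `x2`, `y2`, `d1`, `d2`, `R`,
#'   `stage_kept` (one of `C+inlier`, `C`, for rows of the bidirectional
#'   set).
#'
#' @param pur the `purify` element of a [stitch_images()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(pur, path) {
  C <- pur$C
  df <- data.frame(p_idx = C$p, q_idx = C$q,
                   x1 = C$x1, y1 = C$y1, x2 = C$x2, y2 = C$y2,
                   d1 = C$d1, d2 = C$d2, R = C$R,
                   stage_kept = ifelse(pur$ransac$inlier_mask,
                                       "C+inlier", "C"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a homography as plain text
#'
#' Three whitespace-delimited rows of three numbers (row-major).
#'
#' @param H 3x3 matrix.
#' @param path file path.
#' @return `write_homography`: `path` invisibly; `read_homography`: the
#'   matrix.
#' @export
write_homography <- function(H, path) {
  write.table(format(H, digits = 17), path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_homography
#' @export
read_homography <- function(path) {
  H <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(H) <- NULL
  stopifnot(all(dim(H) == c(3, 3)))
  H
}
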