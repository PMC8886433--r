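# Image containers are plain numeric matrices (grayscale, element [r, c] =
# pixel at 0-based x = c-1, y = r-1) or h x w x 3 arrays (RGB), intensities
# in [0, 1].  Bit depth is carried as the "bitdepth" attribute so a 16-bit
# TIFF survives a round trip.

#' Read an image file
#'
#' Reads a PNG, TIFF or JPEG image and normalizes intensities to `[0, 1]`.
#' Grayscale files come back as a matrix, colour files as an
#' `h x w x 3` array (an alpha channel, if present, is dropped).  The
#' source bit depth (8 or 16) is recorded in the `"bitdepth"` attribute
#' and honoured by [write_image()].
#'
#' @param path file path; format is inferred from the extension
#'   (`.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg`).
#' @return numeric matrix or array with intensities in `[0, 1]`.
#' @seealso [write_image()], [to_gray()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path, info = TRUE),
    tif = ,
    tiff = tiff::readTIFF(path, info = TRUE),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: '", ext, "' (expected PNG, TIFF or JPEG)")
  )
  bits <- 8L
  info <- attr(img, "info")
  b <- if (!is.null(info)) info$bit.depth else attr(img, "bits.per.sample")
  if (!is.null(b) && max(b) > 8) bits <- 16L
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE] else img <- img[, , 1L]
  }
  attributes(img) <- c(attributes(img)[c("dim")], list(bitdepth = bits))
  img
}

#' Write an image file
#'
#' Writes a `[0, 1]` matrix/array as PNG, TIFF or JPEG.  Values are
#' clipped to `[0, 1]`; the bit depth defaults to the image's
#' `"bitdepth"` attribute (see [read_image()]).
#'
#' @param path output path; format inferred from the extension.
#' @param img numeric matrix or `h x w x 3` array in `[0, 1]`.
#' @param bitdepth 8 or 16 (16 only honoured for PNG/TIFF).
#' @return `path`, invisibly.
#' @export
write_image <- function(path, img, bitdepth = NULL) {
  if (is.null(bitdepth)) bitdepth <- attr(img, "bitdepth")
  if (is.null(bitdepth)) bitdepth <- 8L
  x <- pmin(pmax(unclass(img), 0), 1)
  attributes(x) <- attributes(x)["dim"]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = as.integer(bitdepth)),
    jpg = ,
    jpeg = jpeg::writeJPEG(x, path, quality = 0.98),
    stop("unsupported image format: '", ext, "' (expected PNG, TIFF or JPEG)")
  )
  invisible(path)
}

#' Convert an image to grayscale
#'
#' RGB images are reduced with Rec. 601 luminance
#' (`0.299 R + 0.587 G + 0.114 B`); grayscale matrices pass through.
#' Detection always runs on this channel so the 0.03 contrast threshold
#' refers to a fixed intensity scale.
#'
#' @param img matrix or `h x w x 3` array in `[0, 1]`.
#' @return numeric matrix in `[0, 1]`.
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    return(g)
  }
  stop("expected a matrix or an h x w x 3 array")
}

# validate a grayscale image for detection
check_gray_image <- function(img, min_size = 16L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a numeric matrix")
  if (nrow(img) < min_size || ncol(img) < min_size)
    stop("image must be at least ", min_size, "x", min_size, " for detection")
  if (!all(is.finite(img)))
    stop("image contains non-finite intensities")
  if (min(img) < 0 || max(img) > 1)
    stop("intensities must lie in [0, 1]")
  invisible(img)
}
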