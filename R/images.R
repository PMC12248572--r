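#' @import stats utils
#' @importFrom EBImage readImage writeImage Image imageData clahe
NULL

# Internal intensity convention: a grayscale image is a plain numeric matrix
# with values in [0, 255] (8-bit scale); a binary image is a 0/1 integer
# matrix where 1 marks foreground ("white") pixels.

#' Validate a grayscale image matrix
#'
#' @param img object to check.
#' @param arg name used in error messages.
#' @return `img`, invisibly, if valid.
#' @keywords internal
assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0)
    stop(sprintf("`%s` must be a non-empty numeric matrix", arg), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("`%s` must have intensities in [0, 255] without NA", arg),
         call. = FALSE)
  invisible(img)
}

#' Validate a binary image matrix
#' @inheritParams assert_gray
#' @keywords internal
assert_binary <- function(img, arg = "img") {
  if (!is.matrix(img) || length(img) == 0)
    stop(sprintf("`%s` must be a non-empty matrix", arg), call. = FALSE)
  if (!all(img %in% c(0, 1)))
    stop(sprintf("`%s` must contain only 0/1 values", arg), call. = FALSE)
  invisible(img)
}

#' Read an image file as an 8-bit grayscale matrix
#'
#' Reads PNG, TIFF or JPEG. Colour inputs are converted to luminance with the
#' ITU-R BT.601 weights (0.299 R + 0.587 G + 0.114 B). Intensities are
#' rescaled to the [0, 255] convention used throughout the package.
#'
#' @param path file path.
#' @return numeric matrix (rows = image rows) with values in [0, 255].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- EBImage::readImage(path)
  d <- EBImage::imageData(x)   # EBImage stores x = columns first
  if (length(dim(d)) == 3) {
    nch <- dim(d)[3]
    d <- if (nch >= 3) {
      0.299 * d[, , 1] + 0.587 * d[, , 2] + 0.114 * d[, , 3]
    } else d[, , 1]
  }
  img <- t(d) * 255
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

#' Write a grayscale (or binary) matrix as an 8-bit PNG
#'
#' @param img numeric matrix in [0, 255], or a 0/1 binary matrix (written as
#'   0/255).
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  if (all(img %in% c(0, 1))) img <- img * 255
  assert_gray(img)
  # quantize to 8 bits so that disk round-trips are exact
  EBImage::writeImage(EBImage::Image(t(round(img)) / 255), path, type = "png",
                      bits = 8L)
  invisible(path)
}
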