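# Image conditioning: Gaussian blur -> CLAHE -> threshold -> binary mask.
# Blur comes first, matching the batch macro convention of the field's
# tooling; the processed grayscale image is what gets saved to disk, and
# binarization happens on entry to the multifractal stage.

#' Preprocessing configuration
#'
#' Defaults follow the standard OCT conditioning recipe: Gaussian blur with
#' sigma 2 px, CLAHE with block size 127, 256 histogram bins and clip limit
#' 3, then Otsu thresholding.
#'
#' @param sigma blur standard deviation in pixels (> 0).
#' @param clahe_block CLAHE tile size in pixels (odd, >= 3).
#' @param clahe_bins histogram bins (>= 2).
#' @param clahe_clip clip limit, the maximum histogram slope (>= 1).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity in [0, 255], required for
#'   `threshold_method = "fixed"`.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(sigma = 2, clahe_block = 127, clahe_bins = 256,
                              clahe_clip = 3,
                              threshold_method = c("otsu", "fixed"),
                              fixed_threshold = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (clahe_block < 3 || clahe_block %% 2 == 0)
    stop("`clahe_block` must be odd and >= 3", call. = FALSE)
  if (clahe_bins < 2) stop("`clahe_bins` must be >= 2", call. = FALSE)
  if (clahe_clip < 1) stop("`clahe_clip` must be >= 1", call. = FALSE)
  if (threshold_method == "fixed") {
    if (is.null(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 255)
      stop("`fixed_threshold` must be supplied in [0, 255]", call. = FALSE)
  }
  structure(list(sigma = sigma, clahe_block = clahe_block,
                 clahe_bins = clahe_bins, clahe_clip = clahe_clip,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold),
            class = "preprocess_config")
}

# symmetric padding indices of width r: ...c b a | a b c ... | c b a...
.reflect_idx <- function(n, r) {
  if (r >= n) stop("kernel radius exceeds image extent", call. = FALSE)
  c(seq(r, 1), seq_len(n), seq(n, n - r + 1))
}

#' Discrete 2D Gaussian blur
#'
#' Convolution with the separable, renormalized discrete Gaussian kernel
#' \eqn{G(x, y) \propto \exp(-(x^2+y^2)/(2\sigma^2))} evaluated on the
#' integer grid, truncated at radius `ceiling(4 * sigma)` and rescaled to
#' unit sum (truncated mass < 1e-4). Borders use symmetric reflection, which
#' avoids the dark-frame artifacts that zero padding would inject into
#' subsequent box counts.
#'
#' @param img grayscale matrix in [0, 255].
#' @param sigma standard deviation in pixels (> 0).
#' @return blurred matrix, same dimensions, values in [0, 255].
#' @export
gaussian_blur <- function(img, sigma = 2) {
  assert_gray(img)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("`sigma` must be > 0", call. = FALSE)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  conv_cols <- function(m) {
    # symmetric padding along rows, then FIR filter down each column
    ri <- .reflect_idx(nrow(m), r)
    p <- m[ri, , drop = FALSE]
    out <- stats::filter(p, k, method = "convolution", sides = 2)
    out[r + seq_len(nrow(m)), , drop = FALSE]
  }
  out <- t(conv_cols(t(conv_cols(img))))
  out[out < 0] <- 0
  out[out > 255] <- 255
  dimnames(out) <- NULL
  out
}

#' One-dimensional discrete Gaussian kernel (unit sum)
#'
#' @param sigma standard deviation in pixels.
#' @param radius truncation radius; default `ceiling(4 * sigma)`.
#' @return numeric vector of length `2 * radius + 1` summing to 1.
#' @export
gaussian_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit expressed as the
#' maximum slope of the cumulative mapping (the convention of the standard
#' tile-interpolated algorithm). `block` is converted to a tile grid of
#' roughly `block`-sized tiles (at least 2 per axis); the image is padded by
#' symmetric reflection to a tile-divisible size and cropped back, so any
#' image size is accepted.
#'
#' @param img grayscale matrix in [0, 255].
#' @param block tile size in pixels (odd, >= 3).
#' @param bins number of histogram bins.
#' @param clip clip limit / maximum slope (>= 1; 1 disables enhancement).
#' @return equalized matrix in [0, 255], same dimensions as `img`.
#' @export
clahe <- function(img, block = 127, bins = 256, clip = 3) {
  assert_gray(img)
  cfg <- preprocess_config(clahe_block = block, clahe_bins = bins,
                           clahe_clip = clip)  # reuse validation
  ny <- max(2L, round(nrow(img) / block))
  nx <- max(2L, round(ncol(img) / block))
  nr <- ceiling(nrow(img) / ny) * ny
  nc <- ceiling(ncol(img) / nx) * nx
  ri <- c(seq_len(nrow(img)), rev(seq_len(nrow(img))))[seq_len(nr)]
  ci <- c(seq_len(ncol(img)), rev(seq_len(ncol(img))))[seq_len(nc)]
  padded <- img[ri, ci, drop = FALSE]
  out <- EBImage::clahe(EBImage::Image(t(padded) / 255),
                        nx = nx, ny = ny, bins = bins, limit = clip)
  res <- t(EBImage::imageData(out))[seq_len(nrow(img)), seq_len(ncol(img)),
                                    drop = FALSE] * 255
  res[res < 0] <- 0
  res[res > 255] <- 255
  dimnames(res) <- NULL
  res
}

#' Threshold a grayscale image to a binary foreground mask
#'
#' Foreground ("white") pixels are those strictly above the threshold. With
#' `method = "otsu"` the threshold maximizes the between-class variance of
#' the 8-bit histogram; a constant image has no such threshold and yields an
#' all-background mask with a warning rather than an error.
#'
#' @param img grayscale matrix in [0, 255].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold intensity in [0, 255] when `method = "fixed"`.
#' @return 0/1 integer matrix with attribute `"threshold"` recording the
#'   threshold used.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), fixed_threshold = NULL) {
  assert_gray(img)
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 255)
      stop("`fixed_threshold` must be supplied in [0, 255]", call. = FALSE)
    thr <- fixed_threshold
  } else {
    if (diff(range(img)) == 0) {
      warning("constant image: Otsu threshold undefined, returning all-background mask")
      mask <- matrix(0L, nrow(img), ncol(img))
      attr(mask, "threshold") <- NA_real_
      return(mask)
    }
    thr <- EBImage::otsu(EBImage::Image(t(img) / 255), range = c(0, 1),
                         levels = 256) * 255
  }
  mask <- matrix(0L, nrow(img), ncol(img))
  mask[img > thr] <- 1L
  attr(mask, "threshold") <- thr
  mask
}

#' Apply the full conditioning chain to one image
#'
#' Gaussian blur, then CLAHE, in that order. Binarization is not part of the
#' saved image; use [binarize()] (or [extract_features()], which calls it)
#' on the result.
#'
#' @param img grayscale matrix in [0, 255].
#' @param config a [preprocess_config()].
#' @return processed grayscale matrix in [0, 255].
#' @export
preprocess_image <- function(img, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  out <- gaussian_blur(img, config$sigma)
  clahe(out, block = config$clahe_block, bins = config$clahe_bins,
        clip = config$clahe_clip)
}

#' Batch-preprocess an image directory
#'
#' Processes every `.png`, `.tif`/`.tiff` and `.jpg`/`.jpeg` file of
#' `in_dir` in sorted filename order, saving each result as an 8-bit PNG
#' named `<stem>_processed.png` in `out_dir`. Other files, and files that
#' fail to read, are skipped and counted.
#'
#' @param in_dir input directory.
#' @param out_dir output directory (created if missing).
#' @param config a [preprocess_config()].
#' @return list with `processed` and `skipped` counts and the vector of
#'   output paths, invisibly printed as a summary.
#' @export
preprocess_batch <- function(in_dir, out_dir, config = preprocess_config()) {
  if (!dir.exists(in_dir)) stop("input directory not found: ", in_dir,
                                call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- sort(list.files(in_dir))
  is_img <- grepl("\\.(png|tif|tiff|jpg|jpeg)$", files, ignore.case = TRUE)
  processed <- 0L
  skipped <- sum(!is_img)
  outputs <- character(0)
  for (f in files[is_img]) {
    res <- tryCatch({
      img <- read_gray_image(file.path(in_dir, f))
      out <- preprocess_image(img, config)
      stem <- sub("\\.[^.]*$", "", f)
      dest <- file.path(out_dir, paste0(stem, "_processed.png"))
      write_gray_image(out, dest)
      dest
    }, error = function(e) {
      message("skipping unreadable file ", f, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) skipped <- skipped + 1L else {
      processed <- processed + 1L
      outputs <- c(outputs, res)
    }
  }
  list(processed = processed, skipped = skipped, outputs = outputs)
}
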