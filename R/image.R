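#' Integer intensity raster
#'
#' Wraps a matrix of integer pixel intensities with its bit depth. This is
#' the carrier for single-channel angiography frames: 8-bit (`[0, 255]`)
#' by default, 16-bit supported.
#'
#' @param pixels Numeric matrix of integer intensities (rows = image rows).
#' @param bit_depth 8 or 16.
#' @return An object of class `image_grid` with fields `pixels`, `width`,
#'   `height`, `bit_depth`.
#' @export
image_grid <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels) || length(pixels) < 1L)
    abort_degenerate_input("pixels must be a non-empty matrix")
  if (!bit_depth %in% c(8L, 16L))
    abort_degenerate_input(sprintf("unsupported bit depth %s", bit_depth))
  maxv <- 2^bit_depth - 1
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > maxv) ||
      any(pixels != round(pixels)))
    abort_degenerate_input(sprintf(
      "pixel values must be integers in [0, %d]", maxv))
  structure(list(pixels = pixels, width = ncol(pixels),
                 height = nrow(pixels), bit_depth = as.integer(bit_depth)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d, %d-bit, intensity range [%g, %g]\n",
              x$width, x$height, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' @param labels Logical (or 0/1) matrix; `TRUE` marks foreground.
#' @param polarity `"bright_foreground"` (vessels are the bright class,
#'   the ICGA default) or `"dark_foreground"`.
#' @return An object of class `segmentation_mask` with fields `labels`
#'   (logical matrix), `width`, `height`, `polarity`.
#' @export
segmentation_mask <- function(labels,
                              polarity = c("bright_foreground",
                                           "dark_foreground")) {
  polarity <- match.arg(polarity)
  if (!is.matrix(labels) || length(labels) < 1L)
    abort_degenerate_input("labels must be a non-empty matrix")
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      abort_degenerate_input("numeric labels must be 0/1")
    labels <- labels == 1
  }
  if (!is.logical(labels) || anyNA(labels))
    abort_degenerate_input("labels must be logical (or 0/1) with no NA")
  structure(list(labels = labels, width = ncol(labels),
                 height = nrow(labels), polarity = polarity),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d x %d, %s, %d foreground px (%.1f%%)\n",
              x$width, x$height, x$polarity, sum(x$labels),
              100 * mean(x$labels)))
  invisible(x)
}

# Rec. 601 luma conversion for RGB-encoded grayscale exports.
rgb_to_gray <- function(arr) {
  if (dim(arr)[3] >= 3)
    0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  else
    arr[, , 1]
}

#' Read a grayscale image from PNG or TIFF
#'
#' Reads an 8- or 16-bit image and quantizes it to integer intensities.
#' RGB inputs are converted to grayscale with the Rec. 601 luma weights
#' (angiography exports are sometimes RGB-encoded grayscale); an alpha
#' channel, if present, is dropped.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth Target bit depth, 8 (default) or 16.
#' @return An [image_grid()].
#' @export
read_image <- function(path, bit_depth = 8L) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort_degenerate_input(sprintf("unsupported image format '.%s'", ext)))
  if (length(dim(arr)) == 3L) arr <- rgb_to_gray(arr)
  image_grid(round(arr * (2^bit_depth - 1)), bit_depth = bit_depth)
}

#' Write an image or mask to PNG
#'
#' Masks are written as 8-bit PNG with foreground = 255, background = 0,
#' so a written mask reads back losslessly.
#'
#' @param x An [image_grid()] or [segmentation_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  if (inherits(x, "segmentation_mask")) {
    png::writePNG(ifelse(x$labels, 1, 0), path)
  } else if (inherits(x, "image_grid")) {
    png::writePNG(x$pixels / (2^x$bit_depth - 1), path)
  } else {
    abort_degenerate_input("x must be an image_grid or segmentation_mask")
  }
  invisible(path)
}

#' Read a binary mask from a 0/255 PNG
#'
#' @param path PNG path as written by [write_image_png()].
#' @param polarity Polarity tag to attach to the mask.
#' @return A [segmentation_mask()].
#' @export
read_mask <- function(path, polarity = "bright_foreground") {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- rgb_to_gray(arr)
  segmentation_mask(arr > 0.5, polarity = polarity)
}

#' Gray-level histogram of an image
#'
#' Adapter from intensities to the 1-based level convention of the
#' threshold algorithm: a pixel of intensity `v` contributes to level
#' `i = v + 1`, and the histogram has `K = 2^bit_depth` levels.
#'
#' @param img An [image_grid()].
#' @return A [gray_histogram()] with `A = width * height`.
#' @export
image_histogram <- function(img) {
  stopifnot(inherits(img, "image_grid"))
  K <- 2^img$bit_depth
  gray_histogram(tabulate(img$pixels + 1L, nbins = K))
}

#' Optional Gaussian preprocessing
#'
#' Identity by default: the segmentation pipeline applies no smoothing
#' unless an explicit kernel width is given. With `sigma` set, applies an
#' isotropic Gaussian filter of that standard deviation (in pixels) and
#' re-quantizes to the image's bit depth.
#'
#' @param img An [image_grid()].
#' @param sigma Gaussian standard deviation in pixels, or `NULL` (default)
#'   for identity.
#' @return An [image_grid()] of the same size and bit depth.
#' @export
preprocess <- function(img, sigma = NULL) {
  stopifnot(inherits(img, "image_grid"))
  if (is.null(sigma)) return(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    abort_degenerate_input("smoothing sigma must be a positive number")
  maxv <- 2^img$bit_depth - 1
  sm <- EBImage::gblur(img$pixels / maxv, sigma = sigma)
  image_grid(pmin(pmax(round(sm * maxv), 0), maxv),
             bit_depth = img$bit_depth)
}

#' Segment an image at its Otsu threshold
#'
#' Computes the gray-level histogram, selects the Otsu threshold, and
#' labels each pixel. A pixel at level `i` belongs to the low class `B0`
#' iff `i <= round-half-up(t_star)` (the tie-averaged threshold may be
#' fractional, so one documented rounding rule keeps masks reproducible).
#' Under the default `bright_foreground` polarity the high class `B1` is
#' the foreground — ICG fluorescence renders vessels bright;
#' `dark_foreground` selects the low class instead.
#'
#' @param img An [image_grid()]; must not be constant.
#' @param polarity `"bright_foreground"` (default) or `"dark_foreground"`.
#' @param smooth_sigma Optional Gaussian presmoothing SD in pixels
#'   (default none), applied via [preprocess()] before histogramming.
#' @return A list with components `mask` (a [segmentation_mask()]) and
#'   `threshold` (the [otsu_threshold()] result).
#' @examples
#' img <- image_grid(matrix(c(10, 10, 200, 200), 2, 2))
#' seg <- otsu_segment(img)
#' seg$mask$labels
#' @export
otsu_segment <- function(img,
                         polarity = c("bright_foreground",
                                      "dark_foreground"),
                         smooth_sigma = NULL) {
  polarity <- match.arg(polarity)
  img <- preprocess(img, smooth_sigma)
  res <- otsu_threshold(image_histogram(img))
  t_cut <- floor(res$t_star + 0.5)
  low <- (img$pixels + 1L) <= t_cut
  fg <- if (polarity == "bright_foreground") !low else low
  list(mask = segmentation_mask(fg, polarity = polarity), threshold = res)
}
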