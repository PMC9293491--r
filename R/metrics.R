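#' Segmentation and image-quality metrics
#'
#' Pixelwise mean squared error, global structural similarity (SSIM),
#' shape error and the Dice overlap coefficient, for scoring a processed
#' image against the original or a predicted mask against ground truth.
#'
#' @name seg-metrics
NULL

as_pixel_matrix <- function(x) {
  if (inherits(x, "image_grid")) x$pixels
  else if (inherits(x, "segmentation_mask")) x$labels * 1
  else if (is.matrix(x)) x
  else abort_degenerate_input(
    "expected an image_grid, segmentation_mask or matrix")
}

check_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    abort_degenerate_input(sprintf(
      "dimension mismatch: %s vs %s",
      paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
}

#' Mean squared error between two images
#'
#' Mean over all pixels of the squared intensity difference. On masks the
#' intensities are the 0/1 labels.
#'
#' @param a,b Two [image_grid()]s, [segmentation_mask()]s or matrices of
#'   equal dimensions.
#' @return Non-negative scalar; 0 iff identical.
#' @export
mse <- function(a, b) {
  a <- as_pixel_matrix(a); b <- as_pixel_matrix(b)
  check_same_dim(a, b)
  mean((a - b)^2)
}

#' Structural similarity index (SSIM)
#'
#' Global (single-window) SSIM by default:
#' `SSIM = ((2*mx*my + C1) * (2*cov + C2)) /
#'         ((mx^2 + my^2 + C1) * (vx + vy + C2))`
#' with means, population variances and covariance taken over the whole
#' image and stabilizers `C1 = (k1*L)^2`, `C2 = (k2*L)^2`. With `window`
#' set to an odd size, local statistics are computed in sliding square
#' windows (uniform weights) and the mean local SSIM is returned.
#'
#' @param a,b Two images of equal dimensions.
#' @param k1,k2 Stabilizer constants (conventional defaults 0.01, 0.03).
#' @param L Dynamic range; defaults to `2^bit_depth - 1` when `a` is an
#'   `image_grid`, else 255.
#' @param window `NULL` for the global form (default), or an odd window
#'   side length for the sliding-window mean SSIM.
#' @return A scalar in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(a, b, k1 = 0.01, k2 = 0.03, L = NULL, window = NULL) {
  if (is.null(L))
    L <- if (inherits(a, "image_grid")) 2^a$bit_depth - 1 else 255
  if (!is.numeric(L) || L <= 0)
    abort_degenerate_input("dynamic range L must be positive")
  a <- as_pixel_matrix(a); b <- as_pixel_matrix(b)
  check_same_dim(a, b)
  C1 <- (k1 * L)^2
  C2 <- (k2 * L)^2
  if (is.null(window)) {
    mx <- mean(a); my <- mean(b)
    vx <- mean((a - mx)^2); vy <- mean((b - my)^2)
    cov <- mean((a - mx) * (b - my))
    return(((2 * mx * my + C1) * (2 * cov + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  if (window %% 2 != 1 || window < 3 || window > min(dim(a)))
    abort_degenerate_input("window must be odd, >= 3 and fit in the image")
  box <- matrix(1 / window^2, window, window)
  f <- function(m) EBImage::filter2(m, box, boundary = "replicate")
  mx <- f(a); my <- f(b)
  vx <- f(a^2) - mx^2; vy <- f(b^2) - my^2
  cov <- f(a * b) - mx * my
  mean(((2 * mx * my + C1) * (2 * cov + C2)) /
         ((mx^2 + my^2 + C1) * (vx + vy + C2)))
}

#' Shape error of a predicted mask
#'
#' Symmetric-difference area between prediction and ground truth,
#' normalized by the ground-truth area:
#' `SE = |pred XOR truth| / |truth|`. Zero iff the masks are identical;
#' 1 when the prediction is empty; 2 for disjoint equal-area masks. Note
#' the metric is deliberately asymmetric (normalization is by truth).
#'
#' @param pred,truth [segmentation_mask()]s (or logical matrices) of equal
#'   dimensions; `truth` must contain at least one foreground pixel.
#' @return Non-negative scalar.
#' @export
shape_error <- function(pred, truth) {
  p <- as_pixel_matrix(pred) > 0; g <- as_pixel_matrix(truth) > 0
  check_same_dim(p, g)
  if (!any(g))
    abort_degenerate_input("ground-truth mask has no foreground pixels")
  sum(xor(p, g)) / sum(g)
}

#' Dice overlap coefficient
#'
#' `Dice = 2 |pred AND truth| / (|pred| + |truth|)`, in `[0, 1]`; 1 iff
#' the masks are identical and non-empty.
#'
#' @inheritParams shape_error
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  p <- as_pixel_matrix(pred) > 0; g <- as_pixel_matrix(truth) > 0
  check_same_dim(p, g)
  denom <- sum(p) + sum(g)
  if (denom == 0)
    abort_degenerate_input("both masks are empty: Dice undefined")
  2 * sum(p & g) / denom
}

#' Full metric report for a prediction against a reference
#'
#' @param pred,truth Masks (kind `"mask"`) or images (kind `"image"`).
#' @param kind `"mask"` computes MSE on 0/1 labels plus SE and Dice;
#'   `"image"` computes intensity MSE and SSIM only (`se`, `dice` are
#'   `NA`).
#' @return A list of class `metric_report` with fields `mse`, `ssim`,
#'   `se`, `dice`.
#' @export
metric_report <- function(pred, truth, kind = c("mask", "image")) {
  kind <- match.arg(kind)
  if (kind == "mask") {
    structure(list(mse = mse(pred, truth),
                   ssim = ssim(pred, truth, L = 1),
                   se = shape_error(pred, truth),
                   dice = dice(pred, truth)),
              class = "metric_report")
  } else {
    structure(list(mse = mse(pred, truth), ssim = ssim(pred, truth),
                   se = NA_real_, dice = NA_real_),
              class = "metric_report")
  }
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> MSE = %.4g, SSIM = %.4f, SE = %s, Dice = %s\n",
              x$mse, x$ssim,
              if (is.na(x$se)) "NA" else sprintf("%.4f", x$se),
              if (is.na(x$dice)) "NA" else sprintf("%.4f", x$dice)))
  invisible(x)
}
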