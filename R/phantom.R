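#' Specification of a synthetic ICGA phantom
#'
#' Parameter bundle for [generate_phantom()]. The phantom emulates the
#' appearance of an intraoperative ICG fluorescence frame: a bright
#' tubular parent vessel crossing the field with a saccular aneurysm bulge
#' on one side, on a darker background, with optical blur and additive
#' sensor noise producing the bimodal-with-overlap histogram that Otsu
#' thresholding addresses. It emulates the imaging statistics; it does not
#' simulate fluorescence optics or hemodynamics.
#'
#' Aneurysm size classes follow the clinical cut-points: small < 5 mm,
#' medium 5–10 mm, large 10–25 mm, giant > 25 mm.
#'
#' @param width,height Image size in pixels (default 512 x 512).
#' @param pixels_per_mm Spatial scale (default 10, so a 5 mm aneurysm
#'   spans 50 px).
#' @param vessel_width_mm Parent-vessel caliber in mm (default 2.5,
#'   a typical proximal cerebral artery).
#' @param aneurysm_class `"small"`, `"medium"` (default), `"large"` or
#'   `"giant"`.
#' @param aneurysm_diameter_mm Fixed diameter in mm, or `NULL` (default)
#'   to draw uniformly within the class bounds at generation time.
#' @param bg_mean,fg_mean Background / vessel mean intensities (defaults
#'   40 and 180; foreground must be brighter).
#' @param noise_sigma Additive Gaussian noise SD in intensity units
#'   (default 10).
#' @param blur_sigma Gaussian point-spread blur SD in pixels (default 1).
#' @param bit_depth 8 (default) or 16.
#' @param seed Integer RNG seed; the scene is fully determined by it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 512L, height = 512L, pixels_per_mm = 10,
                         vessel_width_mm = 2.5,
                         aneurysm_class = c("medium", "small", "large",
                                            "giant"),
                         aneurysm_diameter_mm = NULL,
                         bg_mean = 40, fg_mean = 180,
                         noise_sigma = 10, blur_sigma = 1,
                         bit_depth = 8L, seed = 1L) {
  aneurysm_class <- match.arg(aneurysm_class)
  if (fg_mean <= bg_mean)
    abort_degenerate_input("fg_mean must exceed bg_mean")
  if (width < 32L || height < 32L)
    abort_degenerate_input("phantom must be at least 32 x 32 pixels")
  if (noise_sigma < 0 || blur_sigma < 0)
    abort_degenerate_input("noise_sigma and blur_sigma must be >= 0")
  if (!is.null(aneurysm_diameter_mm)) {
    b <- aneurysm_class_bounds(aneurysm_class)
    if (aneurysm_diameter_mm < b[1] || aneurysm_diameter_mm > b[2])
      abort_degenerate_input(sprintf(
        "diameter %.2f mm outside class '%s' bounds [%g, %g]",
        aneurysm_diameter_mm, aneurysm_class, b[1], b[2]))
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixels_per_mm = pixels_per_mm,
                 vessel_width_mm = vessel_width_mm,
                 aneurysm_class = aneurysm_class,
                 aneurysm_diameter_mm = aneurysm_diameter_mm,
                 bg_mean = bg_mean, fg_mean = fg_mean,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Diameter bounds in mm per clinical size class; the giant class is capped
# at 35 mm and the small class floored at 1.5 mm so draws stay renderable.
aneurysm_class_bounds <- function(cls) {
  switch(cls,
         small = c(1.5, 5), medium = c(5, 10),
         large = c(10, 25), giant = c(25, 35),
         abort_degenerate_input(sprintf("unknown aneurysm class '%s'", cls)))
}

#' Draw an aneurysm diameter within a size class
#'
#' Uniform draw within the clinical class bounds (small `[1.5, 5)` mm,
#' medium `[5, 10]`, large `(10, 25]`, giant `(25, 35]`), using the
#' current RNG state.
#'
#' @param cls Size class name.
#' @return Diameter in mm.
#' @export
sample_aneurysm_diameter <- function(cls) {
  b <- aneurysm_class_bounds(cls)
  stats::runif(1, b[1], b[2])
}

# Smooth random-walk centerline crossing the image left to right:
# fixed-length steps with AR(1)-damped heading jitter, heading clipped to
# +-45 degrees so the path always progresses.
vessel_centerline <- function(width, height, step = width / 24) {
  x <- 0
  y <- height * stats::runif(1, 0.35, 0.65)
  theta <- 0
  pts <- list(c(x, y))
  while (x <= width) {
    theta <- max(-pi / 4, min(pi / 4, 0.7 * theta + stats::rnorm(1, 0, 0.25)))
    x <- x + step * cos(theta)
    y <- min(max(y + step * sin(theta), height * 0.1), height * 0.9)
    pts[[length(pts) + 1L]] <- c(x, y)
  }
  do.call(rbind, pts)
}

# Minimum distance from every pixel center to a polyline (per-segment
# point-to-segment distance, vectorized over pixels).
polyline_distance <- function(px, py, path) {
  d2 <- rep(Inf, length(px))
  for (k in seq_len(nrow(path) - 1L)) {
    a <- path[k, ]; b <- path[k + 1L, ]
    vx <- b[1] - a[1]; vy <- b[2] - a[2]
    len2 <- vx * vx + vy * vy
    tt <- if (len2 > 0)
      pmin(pmax(((px - a[1]) * vx + (py - a[2]) * vy) / len2, 0), 1)
    else 0
    dx <- px - (a[1] + tt * vx); dy <- py - (a[2] + tt * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# Point on the polyline at a given arc-length fraction, with the local
# unit tangent (for placing the saccular bulge tangent to the path).
point_at_fraction <- function(path, frac) {
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                         path[-nrow(path), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  target <- frac * s[length(s)]
  k <- max(1L, findInterval(target, s, rightmost.closed = TRUE))
  a <- path[k, ]; b <- path[k + 1L, ]
  u <- (target - s[k]) / max(seg[k], .Machine$double.eps)
  tang <- (b - a) / max(seg[k], .Machine$double.eps)
  list(point = a + u * (b - a), tangent = tang)
}

#' Generate a synthetic ICGA phantom scene
#'
#' Renders a smooth random-walk parent vessel of the specified caliber
#' plus a circular saccular bulge whose disc is tangent to the vessel
#' centerline (so it always overlaps the vessel), fills vessel pixels at
#' `fg_mean` and background at `bg_mean`, applies Gaussian blur
#' (`blur_sigma`) then additive Gaussian noise (`noise_sigma`), and clips
#' and rounds to the bit depth. The ground-truth mask is the pre-blur,
#' pre-noise geometry: blur models optics, not anatomy, so metrics score
#' anatomy recovery. The scene is fully determined by `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_scene`: `image` ([image_grid()]),
#'   `truth` ([segmentation_mask()], bright-foreground), `spec` (with the
#'   realized `aneurysm_diameter_mm` filled in), `vessel_path` (centerline
#'   polyline, columns x and y in pixels), `aneurysm_center` (x, y) and
#'   `vessel_radius_px`, `aneurysm_radius_px`.
#' @examples
#' sc <- generate_phantom(phantom_spec(width = 128, height = 128, seed = 7))
#' seg <- otsu_segment(sc$image)
#' dice(seg$mask, sc$truth)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    diam_mm <- spec$aneurysm_diameter_mm %||%
      sample_aneurysm_diameter(spec$aneurysm_class)
    r_px <- diam_mm * spec$pixels_per_mm / 2
    if (2 * r_px > min(spec$width, spec$height))
      abort_degenerate_input(sprintf(
        "aneurysm (%.1f mm = %.0f px) exceeds the image extent",
        diam_mm, 2 * r_px))
    vessel_r <- spec$vessel_width_mm * spec$pixels_per_mm / 2

    path <- vessel_centerline(spec$width, spec$height)
    px <- rep(seq_len(spec$width), each = spec$height)
    py <- rep(seq_len(spec$height), times = spec$width)
    vessel <- polyline_distance(px, py, path) <= vessel_r

    anchor <- point_at_fraction(path, stats::runif(1, 0.35, 0.65))
    side <- sample(c(-1, 1), 1)
    normal <- side * c(-anchor$tangent[2], anchor$tangent[1])
    center <- anchor$point + r_px * normal
    bulge <- (px - center[1])^2 + (py - center[2])^2 <= r_px^2

    truth <- matrix(vessel | bulge, spec$height, spec$width)
    maxv <- 2^spec$bit_depth - 1
    img <- matrix(ifelse(truth, spec$fg_mean, spec$bg_mean),
                  spec$height, spec$width)
    if (spec$blur_sigma > 0)
      img <- EBImage::gblur(img, sigma = spec$blur_sigma)
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                          spec$height, spec$width)
    img <- pmin(pmax(round(img), 0), maxv)

    spec$aneurysm_diameter_mm <- diam_mm
    structure(list(
      image = image_grid(img, bit_depth = spec$bit_depth),
      truth = segmentation_mask(truth, polarity = "bright_foreground"),
      spec = spec, vessel_path = path, aneurysm_center = center,
      vessel_radius_px = vessel_r, aneurysm_radius_px = r_px),
      class = "phantom_scene")
  })
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "<phantom_scene> %d x %d, %s aneurysm %.1f mm, fg/bg %g/%g, noise %g, seed %d\n",
    x$spec$width, x$spec$height, x$spec$aneurysm_class,
    x$spec$aneurysm_diameter_mm, x$spec$fg_mean, x$spec$bg_mean,
    x$spec$noise_sigma, x$spec$seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
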