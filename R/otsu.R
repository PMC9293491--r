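#' Gray-level histogram
#'
#' Constructs the per-level pixel-count histogram that is the sole input
#' statistic of the Otsu threshold-selection algorithm. Gray levels are
#' indexed `1..K`; an 8-bit intensity `v` in `[0, 255]` corresponds to
#' level `i = v + 1` (see [image_histogram()] for the adapter).
#'
#' @param counts Non-negative integer vector of pixel counts per gray
#'   level; `counts[i]` is the number of pixels at level `i`.
#' @return An object of class `gray_histogram` with fields `counts`, `K`
#'   (number of levels) and `A` (total pixel count).
#' @examples
#' h <- gray_histogram(c(5, 0, 0, 5))
#' otsu_threshold(h)$t_star
#' @export
gray_histogram <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L)
    abort_degenerate_input("a histogram needs at least K = 2 gray levels")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    abort_degenerate_input("histogram counts must be non-negative integers")
  structure(list(counts = counts, K = length(counts), A = sum(counts)),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat(sprintf("<gray_histogram> K = %d levels, A = %g pixels, %d occupied\n",
              x$K, x$A, sum(x$counts > 0)))
  invisible(x)
}

#' Normalize a histogram to a probability distribution
#'
#' Divides each count by the total pixel number so the histogram becomes
#' the gray-level probability distribution `q_i = a_i / A`.
#'
#' @param h A [gray_histogram()].
#' @return An object of class `normalized_histogram`: list with `q`
#'   (probabilities, summing to 1) and `K`.
#' @export
normalize_histogram <- function(h) {
  stopifnot(inherits(h, "gray_histogram"))
  if (h$A <= 0)
    abort_degenerate_input("empty histogram: total pixel count A is zero")
  structure(list(q = h$counts / h$A, K = h$K),
            class = "normalized_histogram")
}

#' Zero- and first-order cumulative moments of a normalized histogram
#'
#' Computes the cumulative class probability `omega(t) = sum_{i<=t} q_i`,
#' the cumulative first moment `mu(t) = sum_{i<=t} i q_i`, and the global
#' mean `mu_E = mu(K)`, for thresholds `t = 1..K`.
#'
#' @param q A [normalize_histogram()] result.
#' @return An object of class `cumulative_moments`: `omega`, `mu`
#'   (length-`K` vectors) and `mu_E`.
#' @export
cumulative_moments <- function(q) {
  stopifnot(inherits(q, "normalized_histogram"))
  omega <- cumsum(q$q)
  mu <- cumsum(seq_len(q$K) * q$q)
  structure(list(omega = omega, mu = mu, mu_E = mu[q$K], K = q$K),
            class = "cumulative_moments")
}

# Thresholds t (1 <= t < K) for which both classes are non-empty.
# Computed from raw cumulative probability compared against exact 0/1
# bounds of the running count, not floating-point omega.
admissible_thresholds <- function(h) {
  cc <- cumsum(h$counts)
  t_all <- seq_len(h$K - 1L)
  t_all[cc[t_all] > 0 & cc[t_all] < h$A]
}

check_admissible <- function(q, m, t) {
  if (length(t) != 1L || t != floor(t) || t < 1L || t >= q$K)
    abort_degenerate_split(sprintf(
      "threshold t must be an integer in [1, K-1]; got %s", toString(t)))
  w <- m$omega[t]
  if (w <= 0 || w >= 1)
    abort_degenerate_split(sprintf(
      "t = %d leaves an empty class (omega(t) = %g)", t, w))
  invisible(w)
}

#' Class probabilities, means and variances at a candidate threshold
#'
#' Splits the gray levels into target class `B0` (levels `1..t`) and
#' background class `B1` (levels `t+1..K`) and returns each class's
#' probability, mean and variance. The mixture identities
#' `omega0 + omega1 = 1` and `omega0*mu0 + omega1*mu1 = mu_E` hold for
#' every admissible split.
#'
#' @param q A [normalize_histogram()] result.
#' @param m Matching [cumulative_moments()].
#' @param t Integer candidate threshold, `1 <= t < K`, with both classes
#'   non-empty.
#' @return An object of class `class_statistics`: `t`, `omega0`, `omega1`,
#'   `mu0`, `mu1`, `var0`, `var1`.
#' @export
class_statistics <- function(q, m, t) {
  stopifnot(inherits(q, "normalized_histogram"),
            inherits(m, "cumulative_moments"))
  check_admissible(q, m, t)
  i <- seq_len(q$K)
  omega0 <- m$omega[t]
  omega1 <- 1 - omega0
  mu0 <- m$mu[t] / omega0
  mu1 <- (m$mu_E - m$mu[t]) / omega1
  lo <- i <= t
  var0 <- sum((i[lo] - mu0)^2 * q$q[lo]) / omega0
  var1 <- sum((i[!lo] - mu1)^2 * q$q[!lo]) / omega1
  structure(list(t = t, omega0 = omega0, omega1 = omega1,
                 mu0 = mu0, mu1 = mu1, var0 = var0, var1 = var1),
            class = "class_statistics")
}

#' Within/between/total variance decomposition and separability criteria
#'
#' At threshold `t`, the within-class variance
#' `sigma_V^2 = omega0*sigma0^2 + omega1*sigma1^2`, the between-class
#' variance `sigma_C^2 = omega0*(mu0-mu_E)^2 + omega1*(mu1-mu_E)^2` and
#' the (threshold-independent) total variance `sigma_E^2` satisfy the
#' conservation identity `sigma_V^2 + sigma_C^2 = sigma_E^2`. The three
#' equivalent separability criteria are `lambda = sigma_C^2/sigma_V^2`,
#' `kappa = sigma_E^2/sigma_V^2` and `eta = sigma_C^2/sigma_E^2`;
#' `lambda` and `kappa` are `Inf` when the within-class variance vanishes.
#'
#' @inheritParams class_statistics
#' @return An object of class `variance_decomposition`: `sigma_V2`,
#'   `sigma_C2`, `sigma_E2`, `lambda`, `kappa`, `eta`.
#' @export
variance_decomposition <- function(q, m, t) {
  cs <- class_statistics(q, m, t)
  i <- seq_len(q$K)
  sigma_V2 <- cs$omega0 * cs$var0 + cs$omega1 * cs$var1
  sigma_C2 <- cs$omega0 * (cs$mu0 - m$mu_E)^2 +
    cs$omega1 * (cs$mu1 - m$mu_E)^2
  sigma_E2 <- sum((i - m$mu_E)^2 * q$q)
  if (sigma_E2 <= 0)
    abort_constant_image(
      "total variance is zero (constant image): criteria undefined",
      level = which(q$q > 0)[1L])
  structure(list(
    sigma_V2 = sigma_V2, sigma_C2 = sigma_C2, sigma_E2 = sigma_E2,
    lambda = if (sigma_V2 > 0) sigma_C2 / sigma_V2 else Inf,
    kappa = if (sigma_V2 > 0) sigma_E2 / sigma_V2 else Inf,
    eta = sigma_C2 / sigma_E2),
    class = "variance_decomposition")
}

#' Between-class variance in closed first-order form
#'
#' The fast equivalent of the two-term between-class variance:
#' `sigma_C^2(t) = (mu_E*omega(t) - mu(t))^2 / (omega(t) * (1 - omega(t)))`.
#' Uses only the cumulative moments, no per-class second-order sums, and
#' agrees with [variance_decomposition()]'s `sigma_C2` for every
#' admissible threshold.
#'
#' @param m A [cumulative_moments()] object.
#' @param t Integer candidate threshold with both classes non-empty.
#' @return The between-class variance at `t` (non-negative scalar).
#' @export
between_class_variance <- function(m, t) {
  stopifnot(inherits(m, "cumulative_moments"))
  if (length(t) != 1L || t != floor(t) || t < 1L || t >= m$K)
    abort_degenerate_split(sprintf(
      "threshold t must be an integer in [1, K-1]; got %s", toString(t)))
  w <- m$omega[t]
  denom <- w * (1 - w)
  if (denom <= 0)
    abort_degenerate_split(sprintf(
      "t = %d leaves an empty class (omega(t) = %g)", t, w))
  (m$mu_E * w - m$mu[t])^2 / denom
}

#' Select the Otsu threshold of a gray-level histogram
#'
#' Evaluates the between-class variance `sigma_C^2(t)` over all admissible
#' thresholds (splits leaving both classes non-empty) and returns the
#' maximizer. When several thresholds tie for the maximum (detected at
#' relative tolerance `1e-12`), their arithmetic mean is returned, so the
#' optimal threshold `t_star` may be fractional. Maximizing `sigma_C^2` is
#' equivalent to maximizing the `eta` separability criterion.
#'
#' @param h A [gray_histogram()]; must have at least two occupied levels.
#' @return An object of class `otsu_threshold`: `t_star` (real-valued
#'   optimal threshold in level units `1..K`), `curve` (length-`K` vector
#'   of `sigma_C^2(t)`, `NA` at inadmissible `t`), `tied_levels` (integer
#'   thresholds attaining the maximum), `eta_at_star` (`eta` evaluated at
#'   the admissible integer threshold nearest `t_star`), and `K`.
#' @examples
#' otsu_threshold(gray_histogram(c(50, 0, 0, 0, 0, 0, 0, 50)))
#' @export
otsu_threshold <- function(h) {
  stopifnot(inherits(h, "gray_histogram"))
  q <- normalize_histogram(h)
  m <- cumulative_moments(q)
  adm <- admissible_thresholds(h)
  if (length(adm) == 0L)
    abort_constant_image(
      "histogram has a single occupied level: no threshold exists",
      level = which(h$counts > 0)[1L])
  curve <- rep(NA_real_, h$K)
  w <- m$omega[adm]
  curve[adm] <- (m$mu_E * w - m$mu[adm])^2 / (w * (1 - w))
  s_max <- max(curve[adm])
  tol <- 1e-12 * max(s_max, 1)
  tied <- adm[curve[adm] >= s_max - tol]
  t_star <- mean(tied)
  t_int <- adm[which.min(abs(adm - t_star))]
  structure(list(
    t_star = t_star, curve = curve, tied_levels = tied,
    eta_at_star = variance_decomposition(q, m, t_int)$eta,
    K = h$K),
    class = "otsu_threshold")
}

#' @export
print.otsu_threshold <- function(x, ...) {
  cat(sprintf(
    "<otsu_threshold> t* = %g (levels 1..%d), eta = %.4f, %d tied level%s\n",
    x$t_star, x$K, x$eta_at_star, length(x$tied_levels),
    if (length(x$tied_levels) == 1L) "" else "s"))
  invisible(x)
}
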