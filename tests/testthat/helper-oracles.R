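# Independent oracles: deliberately naive O(K^2) two-pass implementations
# computed straight from the definitional per-class sums, kept free of any
# cumulative-moment shortcut used by the package.

# Between-class variance at threshold t from explicit class sums.
oracle_sigma_C2 <- function(counts, t) {
  q <- counts / sum(counts)
  K <- length(q)
  i <- seq_len(K)
  mu_E <- sum(i * q)
  lo <- i <= t
  w0 <- sum(q[lo]); w1 <- sum(q[!lo])
  if (w0 <= 0 || w1 <= 0) return(NA_real_)
  mu0 <- sum(i[lo] * q[lo]) / w0
  mu1 <- sum(i[!lo] * q[!lo]) / w1
  w0 * (mu0 - mu_E)^2 + w1 * (mu1 - mu_E)^2
}

oracle_eta <- function(counts, t) {
  q <- counts / sum(counts)
  i <- seq_along(q)
  mu_E <- sum(i * q)
  sigma_E2 <- sum((i - mu_E)^2 * q)
  oracle_sigma_C2(counts, t) / sigma_E2
}

# Brute-force threshold selection: argmax of eta over all admissible t,
# exact ties averaged.
oracle_otsu <- function(counts) {
  K <- length(counts)
  vals <- vapply(seq_len(K - 1L), function(t) oracle_eta(counts, t),
                 numeric(1))
  adm <- which(!is.na(vals))
  if (length(adm) == 0L) return(NULL)
  best <- max(vals[adm])
  tied <- adm[vals[adm] >= best - 1e-12 * max(best, 1)]
  list(t_star = mean(tied), tied = tied)
}

# Random histogram with at least two occupied levels.
random_histogram <- function(K, max_count = 20) {
  repeat {
    counts <- sample(0:max_count, K, replace = TRUE)
    if (sum(counts > 0) >= 2L) return(counts)
  }
}

# Exhaustive enumeration of all K-level histograms with counts in `vals`
# and at least two occupied levels, as a matrix (one histogram per row).
enumerate_histograms <- function(K, vals = 0:2) {
  grid <- as.matrix(expand.grid(rep(list(vals), K)))
  grid[rowSums(grid > 0) >= 2L, , drop = FALSE]
}

# Deterministic image pair used to pin SSIM/MSE against an independent
# reference implementation (scikit-image structural_similarity with one
# uniform full-image window and population statistics; values frozen).
ssim_fixture <- function() {
  ij <- expand.grid(i = 0:32, j = 0:32)
  a <- matrix((7 * ij$i + 11 * ij$j) %% 256, 33, 33)
  b <- matrix(a %/% 2 + 60 + 15 * ((ij$i + ij$j) %% 2), 33, 33)
  list(a = a, b = b,
       ssim_ref = 0.7960666289363506, mse_ref = 1393.4398530762167)
}
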