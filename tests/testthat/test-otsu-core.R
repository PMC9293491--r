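test_that("histogram normalization divides counts by the total", {
  expect_equal(normalize_histogram(gray_histogram(c(2, 2)))$q, c(0.5, 0.5))
  expect_equal(normalize_histogram(gray_histogram(c(10, 0, 0, 0)))$q,
               c(1, 0, 0, 0))
  expect_equal(normalize_histogram(gray_histogram(c(1, 2, 3, 4)))$q,
               c(0.1, 0.2, 0.3, 0.4))
  expect_error(normalize_histogram(gray_histogram(c(0, 0))),
               class = "icgaOtsu_degenerate_input")
  expect_error(gray_histogram(c(-1, 2)),
               class = "icgaOtsu_degenerate_input")
  expect_error(gray_histogram(5), class = "icgaOtsu_degenerate_input")
})

test_that("cumulative moments give the running mass, running mean and global mean", {
  m <- cumulative_moments(normalize_histogram(gray_histogram(c(2, 2))))
  expect_equal(m$omega, c(0.5, 1.0))
  expect_equal(m$mu, c(0.5, 1.5))
  expect_equal(m$mu_E, 1.5)
  expect_equal(
    cumulative_moments(normalize_histogram(gray_histogram(c(10, 0, 0, 0))))$mu_E,
    1)
  expect_equal(
    cumulative_moments(normalize_histogram(gray_histogram(c(1, 2, 3, 4))))$mu_E,
    3.0)  # 0.1 + 0.4 + 0.9 + 1.6
})

test_that("cumulative moments satisfy their invariants on random histograms", {
  set.seed(42)
  for (rep in 1:50) {
    q <- normalize_histogram(gray_histogram(random_histogram(16)))
    m <- cumulative_moments(q)
    expect_true(all(diff(m$omega) >= -1e-15))
    expect_equal(m$omega[q$K], 1, tolerance = 1e-12)
    expect_equal(m$mu[q$K], m$mu_E)
    expect_equal(sum(q$q), 1, tolerance = 1e-12)
  }
})

test_that("class statistics match hand-evaluated probabilities and means", {
  qm <- function(counts) {
    q <- normalize_histogram(gray_histogram(counts))
    list(q = q, m = cumulative_moments(q))
  }
  x <- qm(c(1, 1))
  cs <- class_statistics(x$q, x$m, 1)
  expect_equal(cs$omega0, 0.5)
  expect_equal(cs$mu0, 1); expect_equal(cs$mu1, 2)
  expect_equal(cs$var0, 0); expect_equal(cs$var1, 0)

  x <- qm(c(1, 1, 1, 1))
  cs <- class_statistics(x$q, x$m, 2)
  expect_equal(cs$mu0, 1.5); expect_equal(cs$mu1, 3.5)

  x <- qm(c(1, 2, 3, 4))
  cs <- class_statistics(x$q, x$m, 2)
  expect_equal(cs$omega0, 0.3)
  expect_equal(cs$mu0, 5 / 3)

  expect_error(class_statistics(x$q, x$m, 4),
               class = "icgaOtsu_degenerate_split")
  x <- qm(c(0, 5, 5, 0))
  expect_error(class_statistics(x$q, x$m, 1),
               class = "icgaOtsu_degenerate_split")
  expect_error(class_statistics(x$q, x$m, 3),
               class = "icgaOtsu_degenerate_split")
})

test_that("mixture identities hold at every admissible split", {
  set.seed(7)
  for (rep in 1:50) {
    counts <- random_histogram(12)
    q <- normalize_histogram(gray_histogram(counts))
    m <- cumulative_moments(q)
    cc <- cumsum(counts)
    for (t in which(cc[-length(cc)] > 0 & cc[-length(cc)] < sum(counts))) {
      cs <- class_statistics(q, m, t)
      expect_equal(cs$omega0 + cs$omega1, 1, tolerance = 1e-12)
      expect_equal(cs$omega0 * cs$mu0 + cs$omega1 * cs$mu1, m$mu_E,
                   tolerance = 1e-9)
      expect_gte(cs$var0, 0); expect_gte(cs$var1, 0)
    }
  }
})

test_that("variance decomposition matches hand values and conserves total variance", {
  q <- normalize_histogram(gray_histogram(c(1, 1)))
  m <- cumulative_moments(q)
  vd <- variance_decomposition(q, m, 1)
  expect_equal(vd$sigma_C2, 0.25)
  expect_equal(vd$sigma_V2, 0)
  expect_equal(vd$sigma_E2, 0.25)
  expect_equal(vd$eta, 1)
  expect_identical(vd$lambda, Inf)
  expect_identical(vd$kappa, Inf)

  q4 <- normalize_histogram(gray_histogram(c(1, 1, 1, 1)))
  m4 <- cumulative_moments(q4)
  vd4 <- variance_decomposition(q4, m4, 2)
  expect_equal(vd4$eta, oracle_eta(c(1, 1, 1, 1), 2), tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:100) {
    counts <- random_histogram(10)
    q <- normalize_histogram(gray_histogram(counts))
    m <- cumulative_moments(q)
    cc <- cumsum(counts)
    for (t in which(cc[-10] > 0 & cc[-10] < sum(counts))) {
      vd <- variance_decomposition(q, m, t)
      expect_equal(vd$sigma_V2 + vd$sigma_C2, vd$sigma_E2,
                   tolerance = 1e-9)
      expect_true(vd$eta >= 0 && vd$eta <= 1 + 1e-12)
    }
  }
})

test_that("closed-form between-class variance equals the two-term definition", {
  q <- normalize_histogram(gray_histogram(c(1, 1)))
  m <- cumulative_moments(q)
  expect_equal(between_class_variance(m, 1), 0.25)  # (1.5*0.5 - 0.5)^2 / 0.25

  set.seed(99)
  for (rep in 1:1000) {
    counts <- random_histogram(sample(3:20, 1))
    q <- normalize_histogram(gray_histogram(counts))
    m <- cumulative_moments(q)
    cc <- cumsum(counts)
    adm <- which(cc[-length(cc)] > 0 & cc[-length(cc)] < sum(counts))
    for (t in adm) {
      fast <- between_class_variance(m, t)
      slow <- variance_decomposition(q, m, t)$sigma_C2
      expect_equal(fast, slow, tolerance = 1e-9)
    }
  }
})

test_that("between-class variance vanishes when the split leaves the running mean global", {
  # If omega(t) * mu_E = mu(t) the numerator is identically zero.
  m <- structure(list(omega = c(0.5, 1), mu = c(1.25, 2.5), mu_E = 2.5,
                      K = 2L), class = "cumulative_moments")
  expect_equal(between_class_variance(m, 1), 0)
})

test_that("threshold selection averages exact ties and matches hand evaluation", {
  r <- otsu_threshold(gray_histogram(c(5, 0, 0, 5)))
  expect_equal(r$curve[1:3], rep(2.25, 3))
  expect_equal(r$tied_levels, 1:3)
  expect_equal(r$t_star, 2.0)
  expect_equal(r$eta_at_star, 1)

  r8 <- otsu_threshold(gray_histogram(c(50, rep(0, 6), 50)))
  expect_equal(r8$t_star, mean(oracle_otsu(c(50, rep(0, 6), 50))$tied))
  expect_equal(r8$t_star, 4.0)
  expect_equal(r8$tied_levels, 1:7)
})

test_that("threshold selection agrees with the brute-force eta argmax", {
  set.seed(123)
  for (rep in 1:300) {
    counts <- random_histogram(16)
    got <- otsu_threshold(gray_histogram(counts))
    want <- oracle_otsu(counts)
    expect_equal(got$t_star, want$t_star)
    expect_equal(got$tied_levels, want$tied)
  }
})

test_that("threshold is invariant under scaling all counts", {
  set.seed(5)
  for (rep in 1:50) {
    counts <- random_histogram(12)
    base <- otsu_threshold(gray_histogram(counts))
    scaled <- otsu_threshold(gray_histogram(counts * 7))
    expect_equal(scaled$t_star, base$t_star)
    expect_equal(scaled$tied_levels, base$tied_levels)
  }
})

test_that("the three separability criteria share their argmax when within-class variance is positive", {
  set.seed(31)
  done <- 0
  while (done < 30) {
    counts <- random_histogram(10)
    q <- normalize_histogram(gray_histogram(counts))
    m <- cumulative_moments(q)
    cc <- cumsum(counts)
    adm <- which(cc[-10] > 0 & cc[-10] < sum(counts))
    vds <- lapply(adm, function(t) variance_decomposition(q, m, t))
    if (any(vapply(vds, function(v) v$sigma_V2 <= 0, logical(1)))) next
    pick <- function(f) {
      vals <- vapply(vds, f, numeric(1))
      adm[vals >= max(vals) - 1e-12 * max(abs(max(vals)), 1)]
    }
    expect_equal(pick(function(v) v$lambda), pick(function(v) v$sigma_C2))
    expect_equal(pick(function(v) v$eta), pick(function(v) v$sigma_C2))
    done <- done + 1
  }
})

test_that("a constant image raises a dedicated error carrying its level", {
  err <- tryCatch(otsu_threshold(gray_histogram(c(0, 0, 7, 0))),
                  icgaOtsu_constant_image = function(e) e)
  expect_s3_class(err, "icgaOtsu_constant_image")
  expect_equal(err$level, 3L)
})
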