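test_that("normal fit uses sample moments and rejects degenerate data", {
  f <- fit_normal(c(1, 2, 3))
  expect_equal(f$mu, 2)
  expect_equal(f$sigma, 1)
  expect_error(fit_normal(rep(4, 10)), "zero variance")
  expect_error(fit_normal(2), "at least two")
})

test_that("gamma MLE recovers known parameters and matches an independent fitter", {
  x <- sample_gamma(8.5, 0.21, 50000, rng_seed = 99L)
  f <- fit_gamma(x)
  expect_lt(abs(f$shape - 8.5) / 8.5, 0.02)
  expect_lt(abs(f$scale - 0.21) / 0.21, 0.02)
  # profiled-likelihood solution agrees with fitdistrplus on a smaller sample
  skip_if_not_installed("fitdistrplus")
  y <- sample_gamma(3.2, 0.8, 2000, rng_seed = 5L)
  g <- fit_gamma(y)
  ref <- fitdistrplus::fitdist(y, "gamma")$estimate
  expect_equal(g$shape, unname(ref["shape"]), tolerance = 1e-3)
  expect_equal(1 / g$scale, unname(ref["rate"]), tolerance = 1e-3)
  expect_error(fit_gamma(c(0, 1, 2)), "positive")
  expect_error(fit_gamma(rep(2, 10)), "degenerate|converge")
})

test_that("empirical fit keeps the exact step ECDF and smooths by midpoints", {
  f <- fit_empirical(c(1, 2, 3))
  expect_equal(f$step(2), 2 / 3)                     # exact step ECDF
  expect_equal(dist_cdf(f, 1), 0.5 / 3)              # midpoint level at x_(1)
  expect_equal(dist_quantile(f, 0.5), 2)             # linear interpolation inverse
  expect_equal(dist_cdf(f, c(-10, 10)), c(0.5 / 3, 1 - 0.5 / 3))  # flat tails
  # step and smoothed CDF differ by at most 1/n in sup norm
  set.seed(21)
  for (i in 1:20) {
    x <- stats::rgamma(sample(10:200, 1), 3, 1)
    fe <- fit_empirical(x)
    grid <- sort(c(x, stats::runif(300, min(x) - 1, max(x) + 1)))
    expect_lt(max(abs(fe$step(grid) - dist_cdf(fe, grid))), 1 / length(x) + 1e-12)
  }
  # the "right" dialect anchors the CDF at zero on the smallest value
  fr <- fit_empirical(c(1, 2, 3), dialect = "right")
  expect_equal(dist_cdf(fr, 1), 0)
  expect_equal(dist_cdf(fr, 3), 1)
})

test_that("KDE is the exact normal mixture with closed-form CDF", {
  f2 <- fit_kde(c(-1, 1), bandwidth = 1)
  expect_equal(dist_cdf(f2, 0), 0.5)                 # symmetry
  expect_equal(dist_quantile(f2, 0.5), 0, tolerance = 1e-9)
  expect_equal(dist_pdf(f2, 0), mean(dnorm(c(-1, 1))), tolerance = 1e-12)
  # the density integrates to one
  x <- stats::rgamma(40, 4, 2)
  fk <- fit_kde(x, bandwidth = 0.2)
  itg <- stats::integrate(function(t) dist_pdf(fk, t),
                          min(x) - 10 * 0.2, max(x) + 10 * 0.2,
                          rel.tol = 1e-8, subdivisions = 500L)
  expect_equal(itg$value, 1, tolerance = 1e-6)
  # CDF reaches its limits outside data range +- 12 h
  expect_equal(dist_cdf(fk, min(x) - 12 * 0.2), 0, tolerance = 1e-12)
  expect_equal(dist_cdf(fk, max(x) + 12 * 0.2), 1, tolerance = 1e-12)
  expect_error(fit_kde(x, bandwidth = -1), "positive")
})

test_that("default bandwidth follows the normal-reference rule", {
  set.seed(8)
  x <- stats::rnorm(1000)
  h <- default_bandwidth(x)
  expect_lt(abs(h - (4 / 3000)^(1 / 5)) / (4 / 3000)^(1 / 5), 0.10)
  s <- min(stats::sd(x), stats::IQR(x) / 1.349)
  expect_equal(h, s * (4 / (3 * 1000))^(1 / 5), tolerance = 1e-12)
  expect_error(default_bandwidth(rep(1, 5)), "degenerate")
  expect_gt(default_bandwidth(stats::runif(50)), 0)
})

test_that("quantiles invert the CDF for every family", {
  expect_equal(dist_quantile(fit_normal(c(-1, 0, 1)) , 0.5), 0, tolerance = 1e-12)
  # exponential median closed form through the gamma family
  g <- structure(list(family = "gamma", n = 2L, shape = 1, scale = 2),
                 class = c("mir_fit_gamma", "mir_fit"))
  expect_equal(dist_quantile(g, 0.5), 2 * log(2), tolerance = 1e-12)
  expect_error(dist_quantile(g, 1.2), "in \\(0, 1\\)")
  # property: quantile(cdf(x)) = x across random fits of all four families
  set.seed(31)
  for (i in 1:10) {
    x <- stats::rgamma(300, shape = stats::runif(1, 1, 10), scale = stats::runif(1, 0.1, 2))
    fits <- list(fit_normal(x), fit_gamma(x), fit_empirical(x), fit_kde(x))
    for (f in fits) {
      p <- stats::runif(15, 0.02, 0.98)
      q <- dist_quantile(f, p)
      expect_equal(dist_cdf(f, q), p, tolerance = 1e-7)
    }
  }
})

test_that("sampling is reproducible under a seed and follows the fitted law", {
  fits <- list(fit_normal(1:10), fit_gamma(1:10), fit_empirical(1:10),
               fit_kde(1:10, bandwidth = 0.5))
  for (f in fits) {
    expect_identical(dist_sample(f, 25, seed = 4L), dist_sample(f, 25, seed = 4L))
    expect_error(dist_sample(f, 0), "positive count")
  }
  # KDE sampling: support point + h * normal draw; CLT bound on the mean
  fk <- fit_kde(c(0, 0), bandwidth = 1)
  m <- 1e5
  expect_lt(abs(mean(dist_sample(fk, m, seed = 12L))), 3 / sqrt(m))
  # empirical inverse-transform draws stay within the data range
  fe <- fit_empirical(c(2, 3, 9))
  expect_true(all(dist_sample(fe, 1000, seed = 2L) >= 2 &
                    dist_sample(fe, 1000, seed = 2L) <= 9))
})

test_that("percentile tables follow the quantile contract", {
  f <- fit_normal(c(-1, 0, 1))
  tab <- percentile_table(f, c(25, 50, 75))
  expect_equal(tab$value, c(-0.6744898, 0, 0.6744898), tolerance = 1e-6)
  # 100th percentile: maximum of the fitted sample for data-carrying families
  x <- stats::runif(50, 0, 3)
  expect_equal(percentile_table(fit_kde(x, 0.1), 100)$value, max(x))
  expect_equal(percentile_table(fit_empirical(x), 100)$value, max(x))
  expect_error(percentile_table(f, 100), "unbounded")
  expect_error(percentile_table(f, c(50, 101)), "0, 100")
})
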