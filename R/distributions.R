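#' @name fitted-distributions
#' @title Fitted distance distributions
#'
#' @description
#' Four univariate laws are used to model a sample of pairwise distances:
#' the normal distribution, the gamma distribution (shape/scale), the
#' smoothed empirical CDF, and a Gaussian-kernel density estimate. Each fit
#' is an object of class `mir_fit` exposing a common contract —
#' [dist_pdf()], [dist_cdf()], [dist_quantile()], [dist_sample()] — plus
#' [percentile_table()].
NULL

new_fit <- function(family, n, ...) {
  structure(c(list(family = family, n = n), list(...)),
            class = c(paste0("mir_fit_", family), "mir_fit"))
}

#' @export
print.mir_fit <- function(x, ...) {
  par <- switch(x$family,
    normal    = sprintf("mu = %.6g, sigma = %.6g", x$mu, x$sigma),
    gamma     = sprintf("shape = %.6g, scale = %.6g", x$shape, x$scale),
    empirical = sprintf("%d knots, %s dialect", length(x$knots), x$dialect),
    kde       = sprintf("normal kernel, bandwidth = %.6g", x$bandwidth))
  cat(sprintf("<mir_fit> %s (n = %d): %s\n", x$family, x$n, par))
  invisible(x)
}

#' Fit a normal distribution by moments
#'
#' `mu` is the sample mean and `sigma` the sample standard deviation
#' (divisor n−1; at the corpus sizes involved the distinction from the MLE
#' divisor n is far below reporting precision).
#'
#' @param data Numeric sample, `n >= 2`.
#' @return A `mir_fit` of family `"normal"`.
#' @export
fit_normal <- function(data) {
  x <- check_sample(data)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: cannot fit a normal distribution")
  new_fit("normal", length(x), mu = mean(x), sigma = s)
}

#' Fit a gamma distribution by maximum likelihood
#'
#' Shape/scale parameterization (mean = shape × scale), location fixed at 0.
#' The shape solves the profiled score equation
#' `log(a) - digamma(a) = log(mean(x)) - mean(log(x))` by Newton iteration
#' from the standard closed-form starting value, to a tolerance of 1e-10 on
#' the equation; the scale is then `mean(x) / a`.
#'
#' @param data Positive numeric sample, `n >= 2`.
#' @return A `mir_fit` of family `"gamma"`.
#' @export
fit_gamma <- function(data) {
  x <- check_sample(data)
  if (any(x <= 0)) stop("gamma fit requires strictly positive data")
  s <- log(mean(x)) - mean(log(x))
  if (!is.finite(s) || s <= 0) stop("degenerate sample: gamma likelihood unbounded")
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in 1:100) {
    g <- log(a) - digamma(a) - s
    if (abs(g) <= 1e-10) break
    a <- a - g / (1 / a - trigamma(a))
    if (!is.finite(a) || a <= 0) stop("gamma MLE did not converge")
  }
  if (abs(log(a) - digamma(a) - s) > 1e-10) stop("gamma MLE did not converge")
  new_fit("gamma", length(x), shape = a, scale = mean(x) / a)
}

#' Fit the (smoothed) empirical cumulative distribution
#'
#' The step ECDF `F_n(x) = (1/n) * sum(I(x_i <= x))` is retained exactly.
#' The smoothed CDF is its piecewise linear approximation: under the default
#' `"midpoint"` dialect it interpolates the points `(x_(i), (i - 0.5)/n)`,
#' clipped to `[0, 1]` and flat outside the data range; the `"right"`
#' dialect interpolates `(x_(i), i/n)` with a left knot at `x_(1)`.
#' Duplicated order statistics are collapsed to a single knot carrying the
#' highest level, keeping the knot sequence strictly increasing.
#'
#' @param data Numeric sample, `n >= 2`.
#' @param dialect `"midpoint"` (default) or `"right"`.
#' @return A `mir_fit` of family `"empirical"` with elements `step`
#'   (the exact ECDF function), `knots` and `levels`.
#' @export
fit_empirical <- function(data, dialect = c("midpoint", "right")) {
  dialect <- match.arg(dialect)
  x <- sort(check_sample(data))
  n <- length(x)
  lev <- if (dialect == "midpoint") (seq_len(n) - 0.5) / n else seq_len(n) / n
  keep <- !duplicated(x, fromLast = TRUE)  # highest level per distinct value
  knots <- x[keep]; lev <- lev[keep]
  if (length(knots) < 2L) stop("degenerate sample: all values identical")
  if (dialect == "right") lev[1] <- 0  # left anchor: CDF rises from 0 at x_(1)
  new_fit("empirical", n, sorted = x, knots = knots, levels = lev,
          dialect = dialect, step = stats::ecdf(x))
}

#' Fit a Gaussian kernel density estimate
#'
#' The density is the exact normal-kernel mixture
#' `f_h(x) = (1/(n h)) * sum(phi((x - x_i)/h))` and the CDF the closed form
#' `(1/n) * sum(Phi((x - x_i)/h))`; no evaluation grid is involved, so
#' quantiles carry no grid-resolution error. Support is unbounded.
#'
#' @param data Numeric sample, `n >= 2`.
#' @param bandwidth Positive smoothing bandwidth `h`; when `NULL`, the
#'   normal-reference rule of [default_bandwidth()] is used.
#' @return A `mir_fit` of family `"kde"` with elements `points` and
#'   `bandwidth`.
#' @export
fit_kde <- function(data, bandwidth = NULL) {
  x <- check_sample(data)
  h <- if (is.null(bandwidth)) default_bandwidth(x) else bandwidth
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("bandwidth must be a positive number")
  new_fit("kde", length(x), points = x, bandwidth = h)
}

#' Normal-reference bandwidth rule
#'
#' `h = s * (4 / (3 n))^(1/5)` with `s = min(sd(x), IQR(x)/1.349)`, the
#' classical normal-reference choice robustified by the interquartile range.
#'
#' @param data Numeric sample, `n >= 2`.
#' @return Positive bandwidth.
#' @export
default_bandwidth <- function(data) {
  x <- check_sample(data)
  s <- min(stats::sd(x), stats::IQR(x) / 1.349)
  if (s <= 0) stop("degenerate sample: zero spread, no bandwidth")
  s * (4 / (3 * length(x)))^(1 / 5)
}

check_sample <- function(data) {
  x <- as.numeric(data)
  if (length(x) < 2L) stop("need at least two observations")
  if (anyNA(x) || any(!is.finite(x))) stop("sample contains non-finite values")
  x
}

# ---- common contract ------------------------------------------------------

#' Density of a fitted distribution
#' @param fit A `mir_fit`.
#' @param x Numeric vector of evaluation points.
#' @return Density values.
#' @export
dist_pdf <- function(fit, x) UseMethod("dist_pdf")

#' Cumulative distribution function of a fitted distribution
#' @inheritParams dist_pdf
#' @return CDF values in `[0, 1]`.
#' @export
dist_cdf <- function(fit, x) UseMethod("dist_cdf")

#' Quantile function of a fitted distribution
#'
#' Parametric families use their closed-form quantiles; the empirical family
#' inverts its piecewise-linear CDF exactly; the KDE family solves
#' `cdf(x) = p` by bracketed root-finding to `|cdf(x) - p| <= 1e-10`.
#'
#' @param fit A `mir_fit`.
#' @param p Probability levels in (0, 1).
#' @return Quantile values.
#' @export
dist_quantile <- function(fit, p) UseMethod("dist_quantile")

#' Draw a reproducible sample from a fitted distribution
#'
#' Normal/gamma use the standard generators; the empirical family uses
#' inverse-transform sampling on its smoothed CDF; the KDE family picks a
#' support point uniformly and adds `bandwidth` times a standard normal
#' draw.
#'
#' @param fit A `mir_fit`.
#' @param m Number of draws, `m >= 1`.
#' @param seed Optional integer seed (local to this call).
#' @return Numeric vector of length `m`.
#' @export
dist_sample <- function(fit, m, seed = NULL) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) stop("m must be a positive count")
  if (!is.null(seed)) set.seed(seed)
  UseMethod("dist_sample")
}

#' @export
dist_pdf.mir_fit_normal <- function(fit, x) stats::dnorm(x, fit$mu, fit$sigma)
#' @export
dist_cdf.mir_fit_normal <- function(fit, x) stats::pnorm(x, fit$mu, fit$sigma)
#' @export
dist_quantile.mir_fit_normal <- function(fit, p) {
  check_levels(p); stats::qnorm(p, fit$mu, fit$sigma)
}
#' @export
dist_sample.mir_fit_normal <- function(fit, m, seed = NULL) stats::rnorm(m, fit$mu, fit$sigma)

#' @export
dist_pdf.mir_fit_gamma <- function(fit, x) stats::dgamma(x, shape = fit$shape, scale = fit$scale)
#' @export
dist_cdf.mir_fit_gamma <- function(fit, x) stats::pgamma(x, shape = fit$shape, scale = fit$scale)
#' @export
dist_quantile.mir_fit_gamma <- function(fit, p) {
  check_levels(p); stats::qgamma(p, shape = fit$shape, scale = fit$scale)
}
#' @export
dist_sample.mir_fit_gamma <- function(fit, m, seed = NULL) {
  stats::rgamma(m, shape = fit$shape, scale = fit$scale)
}

#' @export
dist_pdf.mir_fit_empirical <- function(fit, x) {
  # derivative of the piecewise-linear CDF (0 outside the knot range)
  k <- fit$knots; l <- fit$levels
  slope <- diff(l) / diff(k)
  i <- findInterval(x, k)
  out <- numeric(length(x))
  inside <- i >= 1L & i < length(k)
  out[inside] <- slope[i[inside]]
  out
}
#' @export
dist_cdf.mir_fit_empirical <- function(fit, x) {
  f <- stats::approxfun(fit$knots, fit$levels, rule = 2)
  pmin(1, pmax(0, f(x)))
}
#' @export
dist_quantile.mir_fit_empirical <- function(fit, p) {
  check_levels(p)
  k <- fit$knots; l <- fit$levels
  inv <- stats::approxfun(l, k, rule = 2, ties = "ordered")
  inv(pmin(max(l), pmax(min(l), p)))
}
#' @export
dist_sample.mir_fit_empirical <- function(fit, m, seed = NULL) {
  dist_quantile(fit, stats::runif(m))
}

#' @export
dist_pdf.mir_fit_kde <- function(fit, x) {
  vapply(x, function(xi) mean(stats::dnorm((xi - fit$points) / fit$bandwidth)) / fit$bandwidth,
         numeric(1))
}
#' @export
dist_cdf.mir_fit_kde <- function(fit, x) {
  vapply(x, function(xi) mean(stats::pnorm((xi - fit$points) / fit$bandwidth)), numeric(1))
}
#' @export
dist_quantile.mir_fit_kde <- function(fit, p) {
  check_levels(p)
  rng <- range(fit$points)
  lo <- rng[1] - 12 * fit$bandwidth
  hi <- rng[2] + 12 * fit$bandwidth
  vapply(p, function(q) {
    r <- stats::uniroot(function(x) dist_cdf(fit, x) - q, c(lo, hi),
                        tol = 1e-12, maxiter = 200L)$root
    stopifnot(abs(dist_cdf(fit, r) - q) <= 1e-8)
    r
  }, numeric(1))
}
#' @export
dist_sample.mir_fit_kde <- function(fit, m, seed = NULL) {
  sample(fit$points, m, replace = TRUE) + fit$bandwidth * stats::rnorm(m)
}

check_levels <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("probability levels must lie strictly in (0, 1)")
  invisible(p)
}

#' Percentile table of a fitted distribution
#'
#' Tabulates `x_q = quantile(fit, q/100)` for the requested percentile
#' levels. For the data-carrying families (empirical, KDE) the 100th
#' percentile is reported as the maximum of the fitted sample; for the
#' parametric families a level of 100 is an error (the quantile is
#' unbounded).
#'
#' @param fit A `mir_fit`.
#' @param levels Percentile levels in (0, 100].
#' @return A `data.frame` with columns `q` and `value`.
#' @export
percentile_table <- function(fit, levels = seq(5, 100, by = 5)) {
  if (any(levels <= 0 | levels > 100)) stop("percentile levels must lie in (0, 100]")
  value <- numeric(length(levels))
  full <- levels == 100
  if (any(full)) {
    if (fit$family %in% c("empirical", "kde")) {
      value[full] <- max(if (fit$family == "kde") fit$points else fit$sorted)
    } else {
      stop("the 100th percentile is unbounded for the ", fit$family, " family")
    }
  }
  if (any(!full)) value[!full] <- dist_quantile(fit, levels[!full] / 100)
  data.frame(q = levels, value = value)
}
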