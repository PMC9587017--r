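#' Two-sample Kolmogorov–Smirnov test
#'
#' Sup-norm distance `D` between the step ECDFs of the two samples, with the
#' asymptotic p-value of the Kolmogorov distribution at effective size
#' `na * nb / (na + nb)` (via [stats::ks.test()] with `exact = FALSE`).
#' Ties between the samples are tolerated (the tie warning is suppressed;
#' the statistic is still the exact sup-norm of the two ECDFs).
#'
#' @param a,b Non-empty numeric samples.
#' @return A list with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Average KS p-value of a fitted distribution over repeated moderate samples
#'
#' The model-selection device for large distance corpora: a two-sample KS
#' test at full corpus size rejects every smooth fit, so instead `m` values
#' are drawn from the fitted law and compared against a reference, and the
#' p-values are averaged over `R` repetitions. Two reference conventions are
#' implemented: `"vs-subsample"` (default) compares against `m` values
#' freshly subsampled without replacement from the observed data each
#' repetition, so both samples are moderate; `"vs-full-data"` compares
#' against the complete observed sample.
#'
#' @param fit A `mir_fit` fitted on `data`.
#' @param data The observed sample the fit refers to.
#' @param m Per-repetition synthetic sample size (default 70).
#' @param R Number of repetitions (default 500).
#' @param mode `"vs-subsample"` or `"vs-full-data"`.
#' @param seed Integer seed making the repetition stream reproducible.
#' @return A one-row `data.frame`: `family`, `avg_p`, `R`, `m`, `mode`, `seed`.
#' @export
average_ks_pvalue <- function(fit, data, m = 70, R = 500,
                              mode = c("vs-subsample", "vs-full-data"),
                              seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(m >= 2, R >= 1)
  if (mode == "vs-subsample" && m > length(data))
    stop("m exceeds the data size for mode vs-subsample")
  refs <- draw_references(data, m, R, mode, seed)
  set.seed(seed)
  p <- vapply(seq_len(R), function(r) {
    ks_two_sample(dist_sample(fit, m), refs[[r]])$p
  }, numeric(1))
  data.frame(family = fit$family, avg_p = mean(p), R = R, m = m,
             mode = mode, seed = seed, stringsAsFactors = FALSE)
}

# Pre-draws the R reference samples from its own seeded stream so that every
# family compared on the same (data, m, R, mode, seed) sees identical
# references, regardless of how many random numbers its own sampler consumes.
draw_references <- function(data, m, R, mode, seed) {
  if (mode == "vs-full-data") return(rep(list(data), R))
  set.seed(seed + 1L)
  lapply(seq_len(R), function(r) data[sample.int(length(data), m)])
}

#' Compare the four candidate families by averaged KS p-values
#'
#' Fits each requested family to `data`, runs [average_ks_pvalue()] for each
#' on the same seeded reference stream, and reports one row per family with
#' an `acceptable` flag for average p-values above 0.05.
#'
#' @param data Observed distance sample.
#' @param families Subset of `c("normal", "gamma", "empirical", "kde")`.
#' @param bandwidth Optional KDE bandwidth override.
#' @param m,R,mode,seed As in [average_ks_pvalue()].
#' @return A `data.frame` (one row per family) with the fitted-parameter
#'   snapshot in the `params` column, sorted in input family order.
#' @export
compare_fits <- function(data, families = c("normal", "gamma", "empirical", "kde"),
                         bandwidth = NULL, m = 70, R = 500,
                         mode = c("vs-subsample", "vs-full-data"), seed = 1L) {
  mode <- match.arg(mode)
  families <- match.arg(families, several.ok = TRUE)
  if (length(data) < m && mode == "vs-subsample") stop("data smaller than m")
  rows <- lapply(families, function(fam) {
    fit <- switch(fam,
                  normal = fit_normal(data),
                  gamma = fit_gamma(data),
                  empirical = fit_empirical(data),
                  kde = fit_kde(data, bandwidth = bandwidth))
    rec <- average_ks_pvalue(fit, data, m = m, R = R, mode = mode, seed = seed)
    rec$params <- switch(fam,
      normal    = sprintf("mu=%.6g sigma=%.6g", fit$mu, fit$sigma),
      gamma     = sprintf("shape=%.6g scale=%.6g", fit$shape, fit$scale),
      empirical = sprintf("dialect=%s", fit$dialect),
      kde       = sprintf("bandwidth=%.6g", fit$bandwidth))
    rec
  })
  out <- do.call(rbind, rows)
  out$acceptable <- out$avg_p > 0.05
  out
}
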