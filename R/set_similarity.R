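#' Defined pairwise distances within a subset of labels
#'
#' Extracts every defined pairwise entry among the given members; missing
#' (`"n/c"`) entries are excluded and counted in the `excluded` attribute.
#'
#' @param m A [dist_matrix()] object.
#' @param members Character vector of at least two labels present in `m`.
#' @return Numeric vector of defined distances with attribute `excluded`
#'   (number of missing member pairs).
#' @export
subset_distances <- function(m, members) {
  stopifnot(inherits(m, "mir_distmat"))
  members <- unique(as.character(members))
  unknown <- setdiff(members, m$labels)
  if (length(unknown)) stop("unknown label(s): ", paste(unknown, collapse = ", "))
  if (length(members) < 2L) stop("need at least two members")
  sub <- m$D[members, members, drop = FALSE]
  v <- sub[lower.tri(sub)]
  out <- v[!is.na(v)]
  if (length(out) == 0L) stop("no defined distances among the members")
  attr(out, "excluded") <- sum(is.na(v))
  out
}

#' Percentile of a subset mean under the reference distribution
#'
#' Places a subset's mean distance on the reference law fitted to all
#' pairwise distances: `100 * cdf(mean_value)`. Small percentiles mean the
#' subset is unusually self-similar relative to miRNAs at large.
#'
#' @param mean_value Subset mean distance.
#' @param ref A `mir_fit` (normally the KDE fit of all distances for the
#'   same substitution model).
#' @return Percentile in `[0, 100]`.
#' @export
set_percentile <- function(mean_value, ref) {
  100 * dist_cdf(ref, mean_value)
}

#' Wilcoxon rank-sum comparison of subset distances against all distances
#'
#' Two-sided Mann–Whitney test with normal approximation and tie correction
#' ([stats::wilcox.test()] with `exact = FALSE`). By default the reference
#' sample is the complete defined-entry list *including* the subset's own
#' values ("subset vs all"); `exclude_subset = TRUE` tests against the
#' complement instead (the p-values differ, so the choice is explicit).
#'
#' @param subset_values Subset distances.
#' @param all_values All defined distances (superset of `subset_values`
#'   unless `exclude_subset = TRUE` is used with a pre-excluded reference).
#' @param exclude_subset Remove one occurrence of each subset value from the
#'   reference before testing.
#' @return Two-sided p-value.
#' @export
ranksum_test <- function(subset_values, all_values, exclude_subset = FALSE) {
  if (length(subset_values) == 0L || length(all_values) == 0L) stop("empty sample")
  ref <- all_values
  if (exclude_subset) {
    idx <- match(subset_values, ref)
    idx <- idx[!is.na(idx)]
    if (length(idx)) ref <- ref[-idx]
    if (length(ref) == 0L) stop("reference empty after excluding the subset")
  }
  if (length(unique(c(subset_values, ref))) == 1L)
    stop("degenerate comparison: all values tied")
  suppressWarnings(stats::wilcox.test(subset_values, ref, exact = FALSE))$p.value
}

#' Full similarity workup of a named miRNA set
#'
#' Matches printed names against the matrix labels ([match_set()]), extracts
#' the subset's defined pairwise distances, and reports — per substitution
#' model — the subset mean, its percentile under the reference law, and the
#' rank-sum p-value against all distances.
#'
#' @param names Printed miRNA names (biomarker panel).
#' @param matrices Named list of [dist_matrix()] objects (e.g.
#'   `list(jc = ..., k2p = ...)`).
#' @param refs Named list of `mir_fit` reference laws, same names as
#'   `matrices`.
#' @param label Text label for the set.
#' @param mapping Optional printed-name to gene-label override table
#'   (see [match_set()]).
#' @param exclude_subset Passed to [ranksum_test()].
#' @return A list of class `mir_setcmp`: `label`, `members`, `unmatched`,
#'   `report` (match audit), and `stats` — a `data.frame` with one row per
#'   model: `model`, `mean`, `percentile`, `p_ranksum`, `n_pairs`,
#'   `n_excluded`.
#' @export
compare_set <- function(names, matrices, refs, label = "set", mapping = NULL,
                        exclude_subset = FALSE) {
  stopifnot(is.list(matrices), is.list(refs),
            setequal(names(matrices), names(refs)))
  ms <- match_set(names, matrices[[1]]$labels, mapping = mapping)
  if (length(ms$matched) < 2L) stop("fewer than two matched members for set '", label, "'")
  stats_rows <- lapply(names(matrices), function(mod) {
    m <- matrices[[mod]]
    d <- subset_distances(m, intersect(ms$matched, m$labels))
    all_d <- dist_values(m)
    data.frame(model = mod,
               mean = mean(d),
               percentile = set_percentile(mean(d), refs[[mod]]),
               p_ranksum = ranksum_test(as.numeric(d), all_d,
                                        exclude_subset = exclude_subset),
               n_pairs = length(d),
               n_excluded = attr(d, "excluded"),
               stringsAsFactors = FALSE)
  })
  structure(list(label = label, members = ms$matched,
                 unmatched = ms$unmatched, report = ms$report,
                 stats = do.call(rbind, stats_rows)),
            class = "mir_setcmp")
}

#' @export
print.mir_setcmp <- function(x, ...) {
  cat(sprintf("<mir_setcmp> '%s': %d members matched, %d unmatched\n",
              x$label, length(x$members), length(x$unmatched)))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Seed-family similarity report
#'
#' Groups sequence records by identical seed (mature positions 2–8) and runs
#' the set-similarity workup for every family with at least two members.
#'
#' @param records Sequence-record data frame carrying seeds.
#' @param matrices,refs As in [compare_set()].
#' @return A `data.frame` with one row per family and model: `family`
#'   (seed motif), `n_members`, plus the [compare_set()] statistics columns.
#' @export
family_report <- function(records, matrices, refs) {
  recs <- records[!is.na(records$seed), , drop = FALSE]
  fams <- split(recs$id, recs$seed)
  fams <- fams[lengths(fams) >= 2L]
  rows <- lapply(names(fams), function(seed) {
    members <- fams[[seed]]
    st <- lapply(names(matrices), function(mod) {
      d <- subset_distances(matrices[[mod]], members)
      data.frame(family = seed, n_members = length(members), model = mod,
                 mean = mean(d),
                 percentile = set_percentile(mean(d), refs[[mod]]),
                 n_pairs = length(d), n_excluded = attr(d, "excluded"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, st)
  })
  do.call(rbind, c(rows, list(NULL)))
}

#' KS comparison of two KDE-smoothed distance distributions
#'
#' Fits a Gaussian KDE to each value list, draws `m` values from each, runs
#' the two-sample KS test, and averages the p-value over `R` seeded
#' repetitions. Used to ask whether a subset's distance distribution (e.g. a
#' seed family's) differs from the corpus-wide one.
#'
#' @param values_a,values_b Distance samples (each fit-able, `n >= 2`).
#' @param m Per-repetition sample size.
#' @param R Repetitions.
#' @param seed Integer seed.
#' @param bandwidth_a,bandwidth_b Optional bandwidth overrides.
#' @return Average p-value over the `R` repetitions.
#' @export
kde_vs_kde_ks <- function(values_a, values_b, m = 70, R = 500, seed = 1L,
                          bandwidth_a = NULL, bandwidth_b = NULL) {
  fa <- fit_kde(values_a, bandwidth = bandwidth_a)
  fb <- fit_kde(values_b, bandwidth = bandwidth_b)
  set.seed(seed)
  mean(vapply(seq_len(R), function(r) {
    ks_two_sample(dist_sample(fa, m), dist_sample(fb, m))$p
  }, numeric(1)))
}
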