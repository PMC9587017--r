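#' Globally align two mature miRNA sequences
#'
#' Needleman–Wunsch global alignment via [Biostrings::pairwiseAlignment()]
#' with the package's default scoring (match +1, mismatch −1, −2 per gap
#' position). Ties between equally scoring alignments are resolved by the
#' deterministic traceback of the underlying dynamic program, so repeated
#' calls give identical alignments. In passthrough mode the inputs are taken
#' as pre-aligned and returned unchanged after a length check.
#'
#' @param s1,s2 RNA sequence strings (gaps `-` allowed in passthrough mode).
#' @param match,mismatch,gap Scoring parameters; `gap` is the (positive)
#'   cost per gap position.
#' @param passthrough If `TRUE`, `s1`/`s2` must be equal-length pre-aligned
#'   rows and are returned as-is.
#' @return A list with gapped strings `a` and `b` of equal length.
#' @export
align_pair <- function(s1, s2, match = 1, mismatch = -1, gap = 2,
                       passthrough = FALSE) {
  if (passthrough) {
    if (nchar(s1) != nchar(s2)) stop("passthrough requires equal-length pre-aligned sequences")
    return(list(a = s1, b = s2))
  }
  if (!nzchar(s1) || !nzchar(s2)) stop("cannot align an empty sequence")
  # align in DNA space (U->T) so the standard nucleotide matrix applies
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(chartr("U", "T", s1), chartr("U", "T", s2),
                                      type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = gap)
  list(a = chartr("T", "U", as.character(Biostrings::alignedPattern(al))),
       b = chartr("T", "U", as.character(Biostrings::alignedSubject(al))))
}

#' Count compared sites, transitions and transversions under pairwise deletion
#'
#' Scans an aligned pair column by column. Columns containing a gap (or any
#' character outside `A`,`C`,`G`,`U`, e.g. a masked `N`) in either row are
#' excluded ("pairwise deletion"). Among the `L` compared columns, a
#' difference is a transition when it swaps `A`<->`G` or `C`<->`U`, and a
#' transversion when it exchanges a purine with a pyrimidine.
#'
#' @param pair A list with equal-length gapped strings `a` and `b`
#'   (as returned by [align_pair()]).
#' @return A list with integer counts `L` (compared sites), `X` (differing
#'   sites), `X1` (transitions) and `X2` (transversions); `X = X1 + X2`.
#' @export
count_sites <- function(pair) {
  a <- strsplit(pair$a, "", fixed = TRUE)[[1]]
  b <- strsplit(pair$b, "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("aligned rows differ in length")
  ok <- a %in% c("A", "C", "G", "U") & b %in% c("A", "C", "G", "U")
  a <- a[ok]; b <- b[ok]
  L <- length(a)
  if (L == 0L) stop("no comparable sites after pairwise deletion")
  diff <- a != b
  purine <- c(A = TRUE, G = TRUE, C = FALSE, U = FALSE)
  ts <- diff & (purine[a] == purine[b])
  list(L = L, X = sum(diff), X1 = sum(ts), X2 = sum(diff & !ts))
}

#' Jukes–Cantor distance from site counts
#'
#' One-parameter distance `K1 = -(3/4) * log(1 - (4/3) * p)` with
#' `p = X / L`, defined only when `1 - (4/3) p > 0` (strict); otherwise the
#' estimate is undefined (`NA`, reported as `"n/c"` in tables). When defined,
#' the approximate sampling variance `(p - p^2) / (L * (1 - (4/3) p)^2)` is
#' attached.
#'
#' @param counts Site counts from [count_sites()].
#' @return A list with `model = "jc"`, `value` (`NA` if undefined) and
#'   `variance` (`NA` if undefined).
#' @export
jc_distance <- function(counts) {
  p <- counts$X / counts$L
  arg <- 1 - 4 / 3 * p
  if (arg <= 0) return(list(model = "jc", value = NA_real_, variance = NA_real_))
  list(model = "jc", value = -3 / 4 * log(arg), variance = jc_variance(counts))
}

#' Sampling variance of the Jukes–Cantor distance
#'
#' @param counts Site counts from [count_sites()].
#' @return `(p - p^2) / (L * (1 - (4/3) p)^2)` with `p = X / L`.
#' @export
jc_variance <- function(counts) {
  p <- counts$X / counts$L
  arg <- 1 - 4 / 3 * p
  if (arg <= 0) stop("JC variance undefined: 1 - (4/3) p <= 0")
  (p - p^2) / (counts$L * arg^2)
}

#' Kimura two-parameter distance from site counts
#'
#' Two-parameter distance
#' `K2 = (1/2) log(1 / (1 - 2P - Q)) + (1/4) log(1 / (1 - 2Q))` with
#' `P = X1 / L` (transitions) and `Q = X2 / L` (transversions), defined only
#' when both `1 - 2P - Q > 0` and `1 - 2Q > 0` (strict). The two conditions
#' are more restrictive than the single Jukes–Cantor condition, which is why
#' fewer pairs have a defined K2P distance.
#'
#' @param counts Site counts from [count_sites()].
#' @return A list with `model = "k2p"` and `value` (`NA` if undefined).
#' @export
k2p_distance <- function(counts) {
  P <- counts$X1 / counts$L
  Q <- counts$X2 / counts$L
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(list(model = "k2p", value = NA_real_))
  list(model = "k2p", value = 0.5 * log(1 / a1) + 0.25 * log(1 / a2))
}

#' Pairwise distance matrix for a set of sequences
#'
#' Computes the chosen model distance for every unordered pair of records.
#' With `aligned = TRUE` the input sequences are rows of a shared multiple
#' alignment (equal lengths, `-` gaps) and each pair is compared directly
#' under pairwise deletion; otherwise every pair is globally aligned first
#' with [align_pair()]. Undefined estimates are stored as missing (`"n/c"`).
#'
#' @param records Sequence-record data frame ([read_fasta()], [new_records()]).
#' @param model `"jc"` or `"k2p"`.
#' @param aligned Treat input as pre-aligned (passthrough per pair).
#' @param ... Scoring parameters forwarded to [align_pair()].
#' @return A [dist_matrix()] object.
#' @export
distance_matrix <- function(records, model = c("jc", "k2p"), aligned = FALSE, ...) {
  model <- match.arg(model)
  n <- nrow(records)
  if (n < 2L) stop("need at least two records")
  if (anyDuplicated(records$id)) stop("duplicate sequence ids")
  if (aligned && length(unique(nchar(records$sequence))) != 1L)
    stop("aligned = TRUE requires equal-length rows")
  D <- matrix(NA_real_, n, n)
  for (j in seq_len(n - 1L)) {
    for (i in seq((j + 1L), n)) {
      pr <- align_pair(records$sequence[j], records$sequence[i],
                       passthrough = aligned, ...)
      est <- switch(model, jc = jc_distance(count_sites(pr)),
                    k2p = k2p_distance(count_sites(pr)))
      D[i, j] <- est$value
    }
  }
  dist_matrix(records$id, D, model)
}
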