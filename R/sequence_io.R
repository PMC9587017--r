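#' Read mature miRNA sequences from a FASTA file
#'
#' Reads a (multi-)FASTA file of mature miRNA sequences into a data frame of
#' sequence records. Sequences are canonicalized to the RNA alphabet
#' (`T`/`t` becomes `U`) and upper-cased. The seed — positions 2–8 (1-based)
#' of the mature sequence, the primary determinant of target recognition — is
#' extracted for every sequence of length at least 8.
#'
#' @param path Path to a FASTA file.
#' @param alphabet How to treat characters outside `A`,`C`,`G`,`U` (after
#'   `T`→`U` canonicalization): `"strict"` rejects the file with an error
#'   naming the offending records; `"mask"` replaces them with `-` so that
#'   pairwise deletion later excludes those sites.
#' @return A `data.frame` with columns `id`, `sequence` and `seed`
#'   (`NA` for sequences shorter than 8 nt). One row per FASTA entry, input
#'   order preserved.
#' @export
read_fasta <- function(path, alphabet = c("strict", "mask")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(chartr("Tt", "Uu", as.character(set)))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    if (alphabet == "strict") {
      stop("non-ACGU characters in record(s): ", paste(ids[bad], collapse = ", "))
    }
    seqs <- gsub("[^ACGU]", "-", seqs)
  }
  new_records(ids, seqs)
}

#' Construct sequence records from ids and sequences
#'
#' @param id Character vector of unique labels.
#' @param sequence Character vector of RNA sequences (may contain `-` gaps).
#' @return A sequence-record `data.frame` (columns `id`, `sequence`, `seed`).
#' @export
new_records <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) stop("duplicate sequence ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  seed <- ifelse(nchar(gsub("-", "", sequence)) >= 8L,
                 substr(gsub("-", "", sequence), 2L, 8L), NA_character_)
  data.frame(id = as.character(id), sequence = as.character(sequence),
             seed = seed, stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records A sequence-record `data.frame` (see [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# ---- distance matrix container -------------------------------------------

#' Labelled pairwise-distance collection with missing entries
#'
#' A lower-triangular collection of pairwise distances between labelled
#' sequences. Entries whose distance is undefined under the substitution
#' model (the model's log argument is non-positive) are stored as `NA` and
#' written out as the textual marker `"n/c"`.
#'
#' @param labels Character vector of N unique labels.
#' @param values N x N numeric matrix; only the lower triangle is used.
#'   `NA` marks an undefined ("n/c") pair.
#' @param model `"jc"` or `"k2p"`.
#' @return An object of class `mir_distmat` with elements `labels`, `D`
#'   (symmetric matrix, `NA` diagonal) and `model`.
#' @export
dist_matrix <- function(labels, values, model = c("jc", "k2p")) {
  model <- match.arg(model)
  labels <- as.character(labels)
  n <- length(labels)
  if (anyDuplicated(labels)) stop("duplicate labels")
  stopifnot(is.matrix(values), nrow(values) == n, ncol(values) == n)
  lower <- values[lower.tri(values)]
  if (any(lower < 0, na.rm = TRUE)) stop("negative distance entries")
  D <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  D[lower.tri(D)] <- lower
  D[upper.tri(D)] <- t(D)[upper.tri(D)]
  structure(list(labels = labels, D = D, model = model), class = "mir_distmat")
}

#' Number of defined (non-missing) pairwise entries
#' @param m A `mir_distmat`.
#' @return Integer count of defined lower-triangular entries.
#' @export
n_defined <- function(m) {
  stopifnot(inherits(m, "mir_distmat"))
  sum(!is.na(m$D[lower.tri(m$D)]))
}

#' All defined pairwise distances of a distance matrix
#' @param m A `mir_distmat`.
#' @return Numeric vector of the defined lower-triangular entries.
#' @export
dist_values <- function(m) {
  stopifnot(inherits(m, "mir_distmat"))
  v <- m$D[lower.tri(m$D)]
  v[!is.na(v)]
}

#' @export
print.mir_distmat <- function(x, ...) {
  n <- length(x$labels)
  npair <- n * (n - 1L) / 2L
  cat(sprintf("<mir_distmat> %s model: %d labels, %d/%d defined pairs (%d n/c)\n",
              toupper(x$model), n, n_defined(x), npair, npair - n_defined(x)))
  invisible(x)
}

# ---- distance table IO ----------------------------------------------------

#' Read a pairwise-distance table
#'
#' Parses a distance table in one of three dialects: `"long"`
#' (`label_a,label_b,distance` rows, the canonical interchange format),
#' `"square"` (full symmetric matrix with labelled rows/columns) or
#' `"lower"` (ragged lower triangle, first column labels). Cells equal to one
#' of `missing_tokens` (case-insensitive; blank cells count too) are stored
#' as missing, mirroring the `"n/c"` marker used for pairs whose distance is
#' undefined under the substitution model.
#'
#' @param path Input file path (CSV, `.` decimal, UTF-8).
#' @param dialect `"long"`, `"square"` or `"lower"`.
#' @param model Substitution model tag stored on the result.
#' @param missing_tokens Character vector of markers denoting an undefined
#'   distance. Default `"n/c"`.
#' @param labels Optional full label set for the long dialect (so that pairs
#'   absent from the file are treated as missing rather than dropped).
#' @param tol Symmetry tolerance for the square dialect.
#' @return A [dist_matrix()] object.
#' @export
read_distance_table <- function(path, dialect = c("long", "square", "lower"),
                                model = c("jc", "k2p"),
                                missing_tokens = "n/c", labels = NULL,
                                tol = 1e-8) {
  dialect <- match.arg(dialect)
  model <- match.arg(model)
  is_missing <- function(x) {
    x <- tolower(trimws(as.character(x)))
    is.na(x) | x == "" | x %in% tolower(missing_tokens)
  }
  as_distance <- function(x, where) {
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) & !is_missing(x)
    if (any(bad)) stop("non-numeric, non-missing cell(s) in ", where, ": ",
                       paste(unique(x[bad]), collapse = ", "))
    v
  }
  if (dialect == "long") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("label_a", "label_b", "distance") %in% names(tab))) {
      stop("long-format table must have header label_a,label_b,distance")
    }
    labs <- if (is.null(labels)) unique(c(tab$label_a, tab$label_b)) else as.character(labels)
    if (anyDuplicated(labs)) stop("duplicate labels")
    n <- length(labs)
    D <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
    if (nrow(tab)) {
      if (any(tab$label_a == tab$label_b)) stop("self-pair in distance table")
      i <- match(tab$label_a, labs); j <- match(tab$label_b, labs)
      if (anyNA(i) || anyNA(j)) stop("pair label absent from supplied label set")
      key <- paste(pmin(i, j), pmax(i, j))
      if (anyDuplicated(key)) stop("duplicate pair rows in distance table")
      D[cbind(i, j)] <- as_distance(tab$distance, "distance column")
      D[cbind(j, i)] <- D[cbind(i, j)]
    }
    return(dist_matrix(labs, D, model))
  }
  if (dialect == "square") {
    tab <- utils::read.csv(path, row.names = 1, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
    labs <- rownames(tab)
    if (anyDuplicated(labs)) stop("duplicate labels")
    if (!identical(labs, colnames(tab))) stop("square table row/column labels differ")
    M <- matrix(as_distance(as.matrix(tab), "square matrix"),
                nrow(tab), ncol(tab), dimnames = list(labs, labs))
    asym <- abs(M - t(M)) > tol
    if (any(asym, na.rm = TRUE) || any(is.na(M) != is.na(t(M))))
      stop("square matrix not symmetric within tolerance ", tol)
    return(dist_matrix(labs, M, model))
  }
  # lower: ragged triangle, row i has label + i-1 cells
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ",", fixed = TRUE)
  labs <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(labs)) stop("duplicate labels")
  n <- length(labs)
  D <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    cells <- parts[[i]][-1L]
    if (length(cells) != i - 1L)
      stop("ragged lower triangle at row ", i, " ('", labs[i], "'): expected ",
           i - 1L, " cells, got ", length(cells))
    if (i > 1L) D[i, seq_len(i - 1L)] <- as_distance(cells, paste0("row ", i))
  }
  dist_matrix(labs, D, model)
}

#' Write a pairwise-distance table
#'
#' Inverse of [read_distance_table()]. The long dialect writes one row per
#' stored pair (`label_a,label_b,distance`) with missing entries emitted as
#' the `"n/c"` token; it round-trips bit-identically through
#' [read_distance_table()].
#'
#' @param m A [dist_matrix()] object.
#' @param path Output path.
#' @param dialect `"long"`, `"square"` or `"lower"`.
#' @param missing_token Marker written for undefined entries.
#' @param digits Significant digits used for formatting (default 15, enough
#'   for bit-exact round trips of double values).
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(m, path, dialect = c("long", "square", "lower"),
                                 missing_token = "n/c", digits = 15) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "mir_distmat"))
  fmt <- function(v) ifelse(is.na(v), missing_token,
                            formatC(v, digits = digits, format = "g"))
  n <- length(m$labels)
  if (dialect == "long") {
    idx <- which(lower.tri(m$D), arr.ind = TRUE)
    out <- data.frame(label_a = m$labels[idx[, 2L]],  # column index = earlier label
                      label_b = m$labels[idx[, 1L]],
                      distance = fmt(m$D[idx]), stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else if (dialect == "square") {
    M <- matrix(fmt(m$D), n, n)
    diag(M) <- "0"
    utils::write.csv(`dimnames<-`(M, list(m$labels, m$labels)), path, quote = FALSE)
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(n)) {
      cells <- if (i > 1L) fmt(m$D[i, seq_len(i - 1L)]) else character()
      writeLines(paste(c(m$labels[i], cells), collapse = ","), con)
    }
  }
  invisible(path)
}

# ---- miRNA name normalization --------------------------------------------

#' Normalize a miRNA name to a family+variant key
#'
#' Maps heterogeneous miRNA spellings — printed biomarker names such as
#' `"miR-21"`, `"let-7a"`, `"miR-19b-5p"` and database-style gene labels such
#' as `"Hsa-Mir-21-P1"` or `"Hsa-Let-7-P2a"` — onto a common key so that
#' printed biomarker panels can be matched against gene labels. The rules,
#' applied in order: lower-case; non-standard hyphens unified; species prefix
#' (`hsa-` or any 3-letter prefix before `mir`/`let`) stripped; arm suffix
#' (`-5p`/`-3p`) stripped; database paralog suffix (`-p<number><letter?>`)
#' stripped; remaining `mir`/`let` spelling kept as-is. The family is the
#' `mir`/`let` stem plus the family number; the variant is the letter (and
#' any `-number` copy index) immediately following the family number.
#'
#' Unparseable names return an "opaque" key equal to the cleaned string, with
#' empty family and variant. The function is idempotent.
#'
#' @param name Character vector of miRNA names.
#' @return A `data.frame` with columns `input`, `key` (family + variant),
#'   `family` and `variant` (empty string when absent).
#' @export
normalize_name <- function(name) {
  raw <- as.character(name)
  x <- tolower(trimws(raw))
  x <- gsub("[‐‑‒–—−]", "-", x)  # unicode hyphens
  x <- gsub("\\s+", "", x)
  x <- sub("^[a-z]{3}-(?=(mir|let))", "", x, perl = TRUE)     # species prefix
  x <- sub("^(mir|let)-?", "\\1-", x)                          # canonical stem-
  x <- sub("-(5p|3p)$", "", x)
  x <- sub("(-p[0-9]+[a-z]?)+$", "", x)                        # database paralog suffix
  m <- regmatches(x, regexec("^(mir|let)-([0-9]+)([a-z]?)(-[0-9]+)?$", x))
  fam <- vapply(m, function(g) if (length(g)) paste0(g[2], "-", g[3]) else "", "")
  var <- vapply(m, function(g) if (length(g)) paste0(g[4], g[5]) else "", "")
  key <- ifelse(nzchar(fam), paste0(fam, var), x)
  data.frame(input = raw, key = key, family = fam, variant = var,
             stringsAsFactors = FALSE)
}

#' Match printed biomarker names against gene labels
#'
#' Matches each printed name to every label whose normalized family matches,
#' using the rule: same family, and the variant letters either agree or one
#' side has none (database paralog labels often omit the variant letter that
#' printed names carry, e.g. `Hsa-Mir-19-P2b` vs `miR-19b`). The mapping is
#' therefore many-to-many; the returned report makes every match inspectable,
#' and a user-supplied `mapping` (data frame `printed_name,gene_label`)
#' overrides the rule for the names it covers.
#'
#' @param names Character vector of printed miRNA names.
#' @param labels Character vector of unique gene labels.
#' @param mapping Optional data frame with columns `printed_name` and
#'   `gene_label`; exact-match override.
#' @return A list with `matched` (character vector of unique matched labels),
#'   `unmatched` (names with no match) and `report` (data frame
#'   `name,label` of every name-label match).
#' @export
match_set <- function(names, labels, mapping = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels")
  if (length(names) == 0L) {
    return(list(matched = character(), unmatched = character(),
                report = data.frame(name = character(), label = character(),
                                    stringsAsFactors = FALSE)))
  }
  nn <- normalize_name(names)
  nl <- normalize_name(labels)
  map_keys <- if (is.null(mapping)) character() else normalize_name(mapping$printed_name)$key
  rows <- lapply(seq_len(nrow(nn)), function(i) {
    if (!is.null(mapping)) {
      ov <- mapping$gene_label[map_keys == nn$key[i]]
      ov <- intersect(ov, labels)
      if (length(ov)) return(data.frame(name = nn$input[i], label = ov,
                                        stringsAsFactors = FALSE))
    }
    hit <- if (nzchar(nn$family[i])) {
      nl$family == nn$family[i] &
        (nl$variant == nn$variant[i] | nl$variant == "" | nn$variant[i] == "")
    } else {
      nl$key == nn$key[i]
    }
    if (any(hit)) data.frame(name = nn$input[i], label = labels[hit],
                             stringsAsFactors = FALSE) else NULL
  })
  report <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(report)) report <- data.frame(name = character(), label = character(),
                                            stringsAsFactors = FALSE)
  list(matched = unique(report$label),
       unmatched = setdiff(nn$input, report$name),
       report = report)
}
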