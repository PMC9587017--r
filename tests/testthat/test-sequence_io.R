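test_that("FASTA reading canonicalizes to RNA and extracts seeds", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">Hsa-Let-7-P1 something", "UGAGGUAGUAGGUUGUAUAGUU",
               ">Hsa-Mir-21-P1", "TAGCTTATCAGACTGATGTTGA",
               ">Short", "ACGU"), fa)
  rec <- read_fasta(fa)
  expect_equal(rec$id, c("Hsa-Let-7-P1", "Hsa-Mir-21-P1", "Short"))
  expect_equal(rec$seed[1], "GAGGUAG")
  expect_equal(rec$sequence[2], "UAGCUUAUCAGACUGAUGUUGA")  # T -> U
  expect_true(is.na(rec$seed[3]))                            # < 8 nt, no seed
  # order preserved, one record per entry
  expect_equal(nrow(rec), 3L)
})

test_that("FASTA alphabet policy: strict rejects, mask gaps out", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">ok", "ACGU", ">badN", "ACNGU"), fa)
  expect_error(read_fasta(fa, alphabet = "strict"), "badN")
  rec <- read_fasta(fa, alphabet = "mask")
  expect_equal(rec$sequence[2], "AC-GU")
  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_fasta(empty), "empty|malformed")
})

test_that("distance tables round-trip through every dialect", {
  m <- fixture_distmat()
  expect_equal(n_defined(m), 5L)
  expect_equal(n_defined(m) + sum(is.na(m$D[lower.tri(m$D)])), 6L)
  for (dialect in c("long", "square", "lower")) {
    f <- tempfile(fileext = ".csv")
    write_distance_table(m, f, dialect)
    m2 <- read_distance_table(f, dialect, model = m$model)
    expect_equal(m2$labels, m$labels)
    expect_equal(m2$D, m$D, tolerance = 1e-12)
    expect_equal(n_defined(m2), 5L)
  }
  # long-format: missing entries written as the n/c token, bit-exact reread
  f <- tempfile(fileext = ".csv")
  write_distance_table(m, f, "long")
  expect_true(any(grepl("n/c", readLines(f), fixed = TRUE)))
  expect_identical(readLines(f),
                   { write_distance_table(read_distance_table(f, "long"), f, "long"); readLines(f) })
})

test_that("table parsing enforces the dialect contracts", {
  f <- tempfile(fileext = ".csv")
  # lower triangle with an n/c cell
  writeLines(c("A", "B,0.5", "C,n/c,1.2"), f)
  m <- read_distance_table(f, "lower")
  expect_equal(n_defined(m), 2L)
  expect_true(is.na(m$D["C", "A"]))
  # ragged triangle
  writeLines(c("A", "B,0.5,9.9", "C,n/c,1.2"), f)
  expect_error(read_distance_table(f, "lower"), "ragged")
  # duplicate labels
  writeLines(c("A", "A,0.5"), f)
  expect_error(read_distance_table(f, "lower"), "duplicate")
  # non-numeric non-missing cell
  writeLines(c("label_a,label_b,distance", "A,B,oops"), f)
  expect_error(read_distance_table(f, "long"), "non-numeric")
  # asymmetric square matrix
  writeLines(c(",A,B", "A,0,0.5", "B,0.7,0"), f)
  expect_error(read_distance_table(f, "square"), "symmetric")
  # empty matrix: header-only long file
  m0 <- dist_matrix(c("A", "B"), matrix(NA_real_, 2, 2), "jc")
  write_distance_table(m0, f, "long")
  expect_equal(n_defined(read_distance_table(f, "long", labels = c("A", "B"))), 0L)
  writeLines("label_a,label_b,distance", f)
  expect_equal(n_defined(read_distance_table(f, "long", labels = c("A", "B"))), 0L)
})

test_that("miRNA name normalization maps printed names and gene labels to one key", {
  expect_equal(normalize_name("miR-21")$key, normalize_name("Hsa-Mir-21")$key)
  n <- normalize_name("let-7a")
  expect_equal(n$family, "let-7")
  expect_equal(n$variant, "a")
  expect_false(normalize_name("miR-19b")$key == normalize_name("miR-19a")$key)
  # database paralog suffixes and arm suffixes are stripped
  expect_equal(normalize_name("Hsa-Mir-19-P2b")$family, "mir-19")
  expect_equal(normalize_name("miR-26b-5p")$key, "mir-26b")
  # idempotent on its own keys, including opaque ones
  inputs <- c("miR-21", "let-7a", "Hsa-Mir-19-P2b", "weird-name-17", "miR-200c")
  keys <- normalize_name(inputs)$key
  expect_equal(normalize_name(keys)$key, keys)
})

test_that("set matching is many-to-many with a full audit and unmatched report", {
  labels <- c("Hsa-Let-7-P1", "Hsa-Let-7-P2a", "Hsa-Mir-21-P1",
              "Hsa-Mir-19-P1", "Hsa-Mir-19-P2b")
  ms <- match_set(c("let-7a", "miR-21", "miR-19b", "miR-999"), labels)
  expect_equal(ms$unmatched, "miR-999")
  # variant-free paralog labels match any printed variant: many-to-many
  expect_true(all(c("Hsa-Mir-19-P1", "Hsa-Mir-19-P2b") %in%
                    ms$report$label[ms$report$name == "miR-19b"]))
  expect_true("Hsa-Mir-21-P1" %in% ms$matched)
  # empty input
  e <- match_set(character(), labels)
  expect_equal(length(e$matched), 0L)
  expect_equal(length(e$unmatched), 0L)
  # user mapping override wins for the names it covers
  ov <- match_set("miR-19b", labels,
                  mapping = data.frame(printed_name = "mir-19b",
                                       gene_label = "Hsa-Mir-19-P2b"))
  expect_equal(ov$matched, "Hsa-Mir-19-P2b")
})
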