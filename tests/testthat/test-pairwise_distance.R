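test_that("global alignment handles identity, terminal gaps and passthrough", {
  al <- align_pair("ACGU", "ACGU")
  expect_equal(al, list(a = "ACGU", b = "ACGU"))
  # one terminal gap is the unique optimal alignment of ACGU vs ACG
  al <- align_pair("ACGU", "ACG")
  expect_equal(nchar(al$a), 4L)
  expect_equal(sum(strsplit(al$b, "")[[1]] == "-"), 1L)
  expect_equal(gsub("-", "", al$b), "ACG")
  # passthrough returns pre-aligned rows unchanged, rejects ragged input
  expect_equal(align_pair("AC-GU", "ACAGU", passthrough = TRUE),
               list(a = "AC-GU", b = "ACAGU"))
  expect_error(align_pair("AC-GU", "ACGU", passthrough = TRUE), "equal-length")
  expect_error(align_pair("", "ACGU"), "empty")
})

test_that("site counting classifies columns under pairwise deletion", {
  expect_equal(count_sites(list(a = "ACGU", b = "ACGA")),
               list(L = 4L, X = 1L, X1 = 0L, X2 = 1L))  # U<->A transversion
  expect_equal(count_sites(list(a = "A-GU", b = "ACGU"))[c("L", "X")],
               list(L = 3L, X = 0L))
  expect_equal(count_sites(list(a = "AG", b = "GA")),
               list(L = 2L, X = 2L, X1 = 2L, X2 = 0L))  # A<->G both transitions
  expect_error(count_sites(list(a = "--", b = "AC")), "no comparable sites")
})

test_that("site counting agrees with the per-column oracle on random gapped pairs", {
  set.seed(7)
  for (i in 1:500) {
    p <- random_gapped_pair()
    got <- tryCatch(count_sites(p), error = function(e) "none")
    want <- oracle_count_sites(p$a, p$b)
    if (identical(got, "none")) {
      expect_equal(want$L, 0L)
    } else {
      expect_equal(got[c("L", "X", "X1", "X2")],
                   want[c("L", "X", "X1", "X2")])
      expect_true(got$X == got$X1 + got$X2 && got$X <= got$L)
    }
  }
})

test_that("JC distance, its validity condition and variance match closed forms", {
  expect_equal(jc_distance(list(L = 22L, X = 0L))$value, 0)
  d <- jc_distance(list(L = 100L, X = 30L))
  expect_equal(d$value, -0.75 * log(0.6), tolerance = 1e-12)
  expect_equal(d$value, 0.3831192, tolerance = 1e-6)
  expect_equal(d$variance, 0.21 / 36, tolerance = 1e-12)
  # p = 3/4 hits the boundary: strictly undefined
  expect_true(is.na(jc_distance(list(L = 100L, X = 75L))$value))
  expect_true(is.na(jc_distance(list(L = 100L, X = 80L))$value))
  expect_equal(jc_variance(list(L = 50L, X = 25L)), 0.045, tolerance = 1e-12)
  expect_equal(jc_variance(list(L = 22L, X = 0L)), 0)
  expect_error(jc_variance(list(L = 100L, X = 75L)), "undefined")
})

test_that("K2P distance matches closed forms and both validity conditions", {
  expect_equal(k2p_distance(list(L = 100L, X = 0L, X1 = 0L, X2 = 0L))$value, 0)
  d <- k2p_distance(list(L = 100L, X = 30L, X1 = 20L, X2 = 10L))
  expect_equal(d$value, 0.5 * log(2) + 0.25 * log(1.25), tolerance = 1e-12)
  expect_equal(d$value, 0.4023595, tolerance = 1e-6)
  # Q = 1/2 violates the second condition
  expect_true(is.na(k2p_distance(list(L = 100L, X = 50L, X1 = 0L, X2 = 50L))$value))
  # 2P + Q = 1 violates the first
  expect_true(is.na(k2p_distance(list(L = 100L, X = 60L, X1 = 40L, X2 = 20L))$value))
})

test_that("JC and K2P coincide when transitions are one third of differences", {
  for (L in c(90L, 300L, 3000L)) {
    for (X in seq(0L, as.integer(0.7 * L), by = as.integer(L / 30))) {
      X1 <- X / 3; X2 <- 2 * X / 3
      cnt <- list(L = L, X = X, X1 = X1, X2 = X2)
      k2 <- k2p_distance(cnt)$value
      k1 <- jc_distance(cnt)$value
      if (!is.na(k1) && !is.na(k2)) expect_equal(k1, k2, tolerance = 1e-12)
    }
  }
})

test_that("JC distance is strictly increasing in X, and K2P-defined implies JC-defined", {
  L <- 200L
  vals <- vapply(0:149, function(X) jc_distance(list(L = L, X = X))$value, numeric(1))
  expect_true(all(diff(vals) > 0))
  # one direction of definedness: JC defined while K2P undefined
  cnt <- list(L = 100L, X = 60L, X1 = 0L, X2 = 60L)
  expect_false(is.na(jc_distance(cnt)$value))
  expect_true(is.na(k2p_distance(cnt)$value))
  # the converse cannot occur: 2P + Q < 1 and Q < 1/2 force p < 3/4.
  set.seed(11)
  for (i in 1:200) {
    X1 <- sample(0:60, 1); X2 <- sample(0:60, 1)
    cnt <- list(L = 100L, X = X1 + X2, X1 = X1, X2 = X2)
    if (!is.na(k2p_distance(cnt)$value)) expect_false(is.na(jc_distance(cnt)$value))
  }
})

test_that("distances agree with an established phylogenetics implementation", {
  skip_if_not_installed("ape")
  set.seed(3)
  for (i in 1:25) {
    n <- sample(18:40, 1)
    a <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
    bin <- ape::as.DNAbin(list(A = strsplit(tolower(chartr("U", "T", a)), "")[[1]],
                               B = strsplit(tolower(chartr("U", "T", b)), "")[[1]]))
    cnt <- count_sites(list(a = a, b = b))
    jc <- jc_distance(cnt)$value
    k2 <- k2p_distance(cnt)$value
    ref_jc <- suppressWarnings(as.numeric(ape::dist.dna(bin, "JC69", pairwise.deletion = TRUE)))
    ref_k2 <- suppressWarnings(as.numeric(ape::dist.dna(bin, "K80", pairwise.deletion = TRUE)))
    if (!is.na(jc) && is.finite(ref_jc)) expect_equal(jc, ref_jc, tolerance = 1e-10)
    if (!is.na(k2) && is.finite(ref_k2)) expect_equal(k2, ref_k2, tolerance = 1e-10)
  }
})

test_that("distance_matrix computes all pairs and propagates undefined entries", {
  recs <- new_records(c("a", "b", "c"), rep("ACGUACGUACGU", 3))
  m <- distance_matrix(recs, "jc")
  expect_equal(n_defined(m), 3L)
  expect_true(all(dist_values(m) == 0))
  # a pair with p >= 3/4 after (trivial) alignment becomes n/c
  far <- new_records(c("x", "y"), c("AAAAAAAAAAAA", "CCCCGGGGUUUU"))
  mf <- distance_matrix(far, "jc", aligned = TRUE)
  expect_equal(n_defined(mf), 0L)
  expect_error(distance_matrix(new_records("a", "ACGU"), "jc"), "two records")
  expect_error(distance_matrix(rbind(recs, recs[1, ]), "jc"))
  # deterministic given inputs
  corpus <- fixture_corpus()[1:10, ]
  m1 <- distance_matrix(corpus, "k2p")
  m2 <- distance_matrix(corpus, "k2p")
  expect_identical(m1$D, m2$D)
  expect_equal(n_defined(m1) + sum(is.na(m1$D[lower.tri(m1$D)])), choose(10, 2))
})

test_that("K2P estimates recover the simulated divergence", {
  # moderate version of the recovery experiment (the acceptance suite runs
  # the full one): d = 0.3, kappa = 2, 60 replicates of length 4000
  reps <- 60
  ests <- vapply(seq_len(reps), function(r) {
    pr <- evolve_pair(sim_config(length = 4000, divergence = 0.3, kappa = 2,
                                 rng_seed = 1000L + r))
    k2p_distance(count_sites(list(a = pr$sequence[1], b = pr$sequence[2])))$value
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(reps)
  expect_lt(abs(mean(ests) - 0.3), 3 * se)
})
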