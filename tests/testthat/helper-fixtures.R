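# Shared fixtures and independent oracles, built in code at test time.

# Brute-force per-column site classification: the oracle for count_sites().
oracle_count_sites <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  L <- 0L; X <- 0L; X1 <- 0L; X2 <- 0L
  purines <- c("A", "G")
  for (i in seq_along(av)) {
    ca <- av[i]; cb <- bv[i]
    if (!(ca %in% c("A", "C", "G", "U")) || !(cb %in% c("A", "C", "G", "U"))) next
    L <- L + 1L
    if (ca != cb) {
      X <- X + 1L
      if ((ca %in% purines) == (cb %in% purines)) X1 <- X1 + 1L else X2 <- X2 + 1L
    }
  }
  list(L = L, X = X, X1 = X1, X2 = X2)
}

# Random gapped sequence pair over ACGU- (possibly with N), aligned rows.
random_gapped_pair <- function(len = 25, gap_p = 0.15, n_p = 0.05) {
  draw <- function() {
    chars <- sample(c("A", "C", "G", "U", "-", "N"), len, replace = TRUE,
                    prob = c(rep((1 - gap_p - n_p) / 4, 4), gap_p, n_p))
    paste(chars, collapse = "")
  }
  list(a = draw(), b = draw())
}

# Brute-force two-sample KS statistic: sup over all jump points of both ECDFs.
oracle_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Small labelled distance matrix with one missing entry.
fixture_distmat <- function(model = "jc") {
  labs <- c("Sim-Mir-1-P1", "Sim-Mir-1-P2", "Sim-Mir-2-P1", "Sim-Mir-2-P2")
  D <- matrix(NA_real_, 4, 4)
  D[lower.tri(D)] <- c(0.10, 1.20, 1.35, 1.10, NA, 0.20)
  dist_matrix(labs, D, model)
}

# Simulated corpus: three seed families plus one fast-evolving background
# family, the sequence-level fixture for end-to-end set analyses.
fixture_corpus <- function(seed = 42L) {
  make_dataset(list(
    sim_config(n_sequences = 8, length = 22, divergence = 0.10, kappa = 2,
               seed_motif = "GAGGUAG", label = "Sim-Let-7", rng_seed = seed),
    sim_config(n_sequences = 5, length = 22, divergence = 0.15, kappa = 2,
               seed_motif = "GGAAUGU", label = "Sim-Mir-1", rng_seed = seed + 1L),
    sim_config(n_sequences = 4, length = 22, divergence = 0, kappa = 2,
               seed_motif = "GGAAGAC", label = "Sim-Mir-7", rng_seed = seed + 2L),
    sim_config(n_sequences = 25, length = 22, divergence = 1.6, kappa = 2,
               seed_motif = "ACGUACG", label = "Sim-Mir-9", rng_seed = seed + 3L)))
}
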