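#' Simulation configuration
#'
#' Conditions for the sequence-evolution simulator. Divergence `d` is the
#' TOTAL expected number of substitutions per site separating the two
#' endpoints (the quantity the JC/K2P distances estimate), split evenly over
#' the two branches from the common ancestor. `kappa` is the
#' transition/transversion *rate* ratio: with `kappa = 1` the transition
#' rate equals each single transversion rate and the process is the
#' one-parameter (JC) model.
#'
#' @param n_sequences Number of sequences (for [make_family()]).
#' @param length Sites per sequence; default 22, the typical mature-miRNA
#'   length.
#' @param divergence `d >= 0`, expected substitutions/site between any two
#'   simulated relatives.
#' @param kappa Transition/transversion rate ratio, `> 0`.
#' @param seed_motif Optional 7-mer over `ACGU` held invariant at mature
#'   positions 2–8.
#' @param label Label stem for generated records.
#' @param rng_seed Integer seed.
#' @return A list of class `mir_simconfig`.
#' @export
sim_config <- function(n_sequences = 2L, length = 22L, divergence = 0.3,
                       kappa = 1, seed_motif = NULL, label = "Sim-Mir-1",
                       rng_seed = 1L) {
  stopifnot(divergence >= 0, kappa > 0, length >= 1, n_sequences >= 1)
  if (!is.null(seed_motif)) {
    if (nchar(seed_motif) != 7L || grepl("[^ACGU]", seed_motif))
      stop("seed_motif must be a 7-mer over ACGU")
    if (length < 8L) stop("length must be >= 8 when seed_motif is set")
  }
  structure(list(n_sequences = as.integer(n_sequences), length = as.integer(length),
                 divergence = divergence, kappa = kappa, seed_motif = seed_motif,
                 label = label, rng_seed = as.integer(rng_seed)),
            class = "mir_simconfig")
}

#' Exact K2P substitution probabilities at a given branch length
#'
#' Closed-form transition-probability entries of the Kimura two-parameter
#' matrix exponential at branch length `d` (expected substitutions/site)
#' and rate ratio `kappa`: the probability that a site shows a transition,
#' each of the two possible transversions, or no change. `kappa = 1`
#' recovers the one-parameter (JC) probabilities.
#'
#' @param d Branch length (expected substitutions per site).
#' @param kappa Transition/transversion rate ratio.
#' @return Named numeric vector `c(same, ts, tv)` where `tv` is the TOTAL
#'   transversion probability (split evenly over the two target bases).
#' @export
k2p_site_probs <- function(d, kappa = 1) {
  # rates: transition alpha, each transversion beta, alpha/beta = kappa,
  # total rate alpha + 2 beta = 1 per unit branch length
  b <- d / (kappa + 2)
  a <- kappa * b
  e1 <- exp(-4 * b)                # 4*beta*t
  e2 <- exp(-2 * (a + b))          # 2*(alpha+beta)*t
  ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  tv <- 0.5 - 0.5 * e1
  c(same = 1 - ts - tv, ts = ts, tv = tv)
}

BASES <- c("A", "C", "G", "U")
TS_MAP <- c(A = "G", G = "A", C = "U", U = "C")
TV_MAP <- list(A = c("C", "U"), G = c("C", "U"), C = c("A", "G"), U = c("A", "G"))

# evolve a character vector of sites along one branch of length d
evolve_branch <- function(sites, d, kappa) {
  if (d == 0) return(sites)
  pr <- k2p_site_probs(d, kappa)
  fate <- sample(c("same", "ts", "tv"), length(sites), replace = TRUE, prob = pr)
  out <- sites
  is_ts <- fate == "ts"
  out[is_ts] <- TS_MAP[sites[is_ts]]
  is_tv <- which(fate == "tv")
  if (length(is_tv)) {
    pick <- stats::runif(length(is_tv)) < 0.5
    out[is_tv] <- vapply(seq_along(is_tv), function(k) {
      TV_MAP[[sites[is_tv[k]]]][if (pick[k]) 1L else 2L]
    }, "")
  }
  out
}

random_ancestor <- function(len, motif = NULL) {
  sites <- sample(BASES, len, replace = TRUE)
  if (!is.null(motif)) sites[2:8] <- strsplit(motif, "")[[1]]
  sites
}

#' Simulate one diverged sequence pair
#'
#' Draws a uniform-random ancestor and evolves two descendants
#' independently, each along a branch of length `divergence / 2`, using the
#' exact K2P matrix-exponential probabilities (no per-generation
#' discretization). The two endpoints are then separated by the configured
#' total divergence in expectation.
#'
#' @param cfg A [sim_config()].
#' @return A two-row sequence-record data frame.
#' @export
evolve_pair <- function(cfg) {
  stopifnot(inherits(cfg, "mir_simconfig"))
  set.seed(cfg$rng_seed)
  anc <- random_ancestor(cfg$length, cfg$seed_motif)
  half <- cfg$divergence / 2
  a <- evolve_branch(anc, half, cfg$kappa)
  b <- evolve_branch(anc, half, cfg$kappa)
  if (!is.null(cfg$seed_motif)) { a[2:8] <- anc[2:8]; b[2:8] <- anc[2:8] }
  new_records(paste0(cfg$label, c("-a", "-b")),
              c(paste(a, collapse = ""), paste(b, collapse = "")))
}

#' Simulate a seed family
#'
#' Generates `n_sequences` relatives of a common family ancestor, all
#' carrying the configured seed motif at mature positions 2–8 (the seed is
#' held invariant, emulating the strong conservation of the target-binding
#' region); non-seed positions evolve independently along branches of
#' length `divergence / 2`, so any two members are separated by the
#' configured divergence *per evolving site* in expectation — averaged over
#' the whole mature sequence the expected distance is
#' `divergence * (length - 7) / length`, because the seed contributes no
#' substitutions. Labels follow a database-style scheme `<label>-P<i>`
#' compatible with [normalize_name()].
#'
#' @param cfg A [sim_config()] with `seed_motif` set.
#' @return A sequence-record data frame with `n_sequences` rows.
#' @export
make_family <- function(cfg) {
  stopifnot(inherits(cfg, "mir_simconfig"))
  if (is.null(cfg$seed_motif)) stop("make_family requires a seed_motif")
  set.seed(cfg$rng_seed)
  anc <- random_ancestor(cfg$length, cfg$seed_motif)
  seqs <- vapply(seq_len(cfg$n_sequences), function(i) {
    s <- evolve_branch(anc, cfg$divergence / 2, cfg$kappa)
    s[2:8] <- anc[2:8]
    paste(s, collapse = "")
  }, "")
  new_records(paste0(cfg$label, "-P", seq_len(cfg$n_sequences)), seqs)
}

#' Assemble a simulated dataset from several configurations
#'
#' @param cfgs Non-empty list of [sim_config()] objects (each with its own
#'   `rng_seed` and `label`).
#' @return Row-bound sequence records; label collisions are an error.
#' @export
make_dataset <- function(cfgs) {
  if (length(cfgs) == 0L) stop("empty configuration list")
  recs <- do.call(rbind, lapply(cfgs, make_family))
  if (anyDuplicated(recs$id)) stop("label collision across configurations")
  recs
}

#' Reproducible gamma sample
#'
#' i.i.d. draws from Gamma(shape `alpha`, scale `beta`), for fit-recovery
#' experiments.
#'
#' @param alpha,beta Positive shape and scale.
#' @param n Sample size.
#' @param rng_seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_gamma <- function(alpha, beta, n, rng_seed = 1L) {
  stopifnot(alpha > 0, beta > 0, n >= 1)
  set.seed(rng_seed)
  stats::rgamma(n, shape = alpha, scale = beta)
}
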