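# mirdist

Distance distributions of human mature miRNAs: an analysis pipeline that
derives the distribution of pairwise evolutionary distances across a corpus
of mature microRNA sequences and uses it to judge how self-similar a named
miRNA subset (a disease biomarker panel, a seed family) is.

## The science

Mature miRNAs are ~22-nt RNAs. For an aligned pair, after removing columns
with a gap in either row (pairwise deletion, leaving `L` sites with `X`
differences, `X1` transitions and `X2` transversions), two classical
substitution-model distances are computed, with `p̂ = X/L`, `P̂ = X1/L`,
`Q̂ = X2/L`:

```
Jukes–Cantor:   K1 = -(3/4) ln(1 - (4/3) p̂)            valid iff 1 - (4/3)p̂ > 0
                V(K1) = (p̂ - p̂²) / (L (1 - (4/3)p̂)²)
Kimura 2-param: K2 = ½ ln(1/(1 - 2P̂ - Q̂)) + ¼ ln(1/(1 - 2Q̂))
                valid iff 1 - 2P̂ - Q̂ > 0 and 1 - 2Q̂ > 0
```

Pairs violating a validity condition are carried as the `n/c` marker. The
corpus-wide samples of defined distances are then fitted by four families —
normal `N(μ, σ²)`, gamma `Γ(α, β)` (shape/scale MLE), a smoothed empirical
CDF (piecewise-linear through `(x₍ᵢ₎, (i−0.5)/n)`), and a Gaussian KDE
`f̂_h(x) = (nh)⁻¹ Σ K((x−xᵢ)/h)` with closed-form CDF — and ranked by the
average p-value of 500 repetitions of a two-sample Kolmogorov–Smirnov test
on 70 drawn values versus 70 subsampled observations (a full-size KS test
rejects every smooth fit). A subset of miRNAs is scored by the mean of its
pairwise distances, the percentile `100·F̂(mean)` of that mean under the
corpus KDE law, and a Wilcoxon rank-sum test against all distances.

Because the underlying corpus (567 human MirGeneDB 2.1 genes; 62,435 JC and
17,519 K2P defined pairs) is not redistributable, the package reconstructs a
**synthetic** surrogate corpus from the published 20-level KDE percentile
tables (with a first-order deconvolution of the kernel smoothing), and ships
a sequence-evolution simulator (exact K2P transition probabilities, seed
motifs held invariant) so every pipeline stage is exercised end to end
without any download.

## Worked example

```r
library(mirdist)

# simulate a 4-member seed family (seed GAGGUAG held at positions 2-8)
fam <- make_family(sim_config(n_sequences = 4, length = 22, divergence = 0.25,
                              kappa = 2, seed_motif = "GAGGUAG",
                              label = "Sim-Let-7", rng_seed = 11L))
m <- distance_matrix(fam, "jc")
m
#> <mir_distmat> JC model: 4 labels, 6/6 defined pairs (0 n/c)

round(m$D, 4)
#>              Sim-Let-7-P1 Sim-Let-7-P2 Sim-Let-7-P3 Sim-Let-7-P4
#> Sim-Let-7-P1           NA       0.0000       0.0469       0.0000
#> Sim-Let-7-P2       0.0000           NA       0.0469       0.0000
#> Sim-Let-7-P3       0.0469       0.0469           NA       0.0469
#> Sim-Let-7-P4       0.0000       0.0000       0.0469           NA

# reference law: KDE of the reconstructed corpus at the published bandwidth
k <- fit_kde(reconstruct_corpus("jc"), bandwidth = corpus_reference("jc")$bandwidth)
k
#> <mir_fit> kde (n = 62435): normal kernel, bandwidth = 0.0836826

fam_mean <- mean(subset_distances(m, fam$id))
c(mean = fam_mean, percentile = set_percentile(fam_mean, k))
#>       mean percentile 
#> 0.02344513 0.24327514
```

Three of the six pairs are identical (distance 0) and the others differ at
one site (K1 ≈ 0.0469 at L = 22), so the family's mean distance 0.0234 sits
at the 0.24th percentile of the corpus-wide law — the family is far more
self-similar than miRNA pairs at large, the same verdict the published seed
families receive.

The numbered scripts under `analysis/` run the full study in order:
`01_reconstruct_corpus.R` (synthetic corpus + simulated sequence families),
`02_pairwise_distances.R`, `03_fit_distributions.R` (fits and KDE percentile
tables), `04_goodness_of_fit.R` (averaged-KS model ranking),
`05_set_similarity.R` (panel placements, family report, KDE-vs-KDE KS);
each writes its tables under `results/`.

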