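# ndsnf — multi-omic cancer subtyping with network-diffused mutation profiles

`ndsnf` discovers cancer subtypes by integrating continuous omics layers
(DNA methylation, mRNA and miRNA expression) **together with binary somatic
mutation data** in one patient similarity network. It is aimed at
computational biologists who have a multi-omic tumor cohort and want subtype
calls that actually use the mutation calls, instead of discarding them
because they are too sparse for any conventional distance.

## The method

Somatic mutation matrices are extremely sparse (typically fewer than 100
mutated genes out of ~10,000 per patient), so two clinically similar
patients rarely share even a single mutated gene and Euclidean or binary
similarity measures carry almost no signal. `ndsnf` fixes this in two
steps:

**1. Network diffusion.** The binary patient-by-gene matrix F₀ is smoothed
over a gene interaction network by random walk with restart,

    F(t+1) = α · F(t) · A + (1 − α) · F₀,

where A is the degree-normalized adjacency of the network and α ∈ [0.5, 0.8]
controls how far the mutation signal propagates. Iteration runs to
convergence (max |F(t+1) − F(t)| < 10⁻⁶; the map is a contraction, so this
always terminates). The result is a quantitative profile in which not only
the mutated genes but also their network neighbours carry signal — patient
similarity becomes mutational consistency at the *pathway* level.

**2. Similarity network fusion (SNF).** Each data layer (the continuous
omics and the smoothed mutation profiles) is turned into a patient affinity
matrix with the scaled exponential kernel

    W(i,j) = exp( −ρ²(xᵢ, xⱼ) / (μ · ε(i,j)) ),

whose bandwidth ε(i,j) adapts to the mean distance of i and j to their K
nearest neighbours. Two row-stochastic derivatives — the full kernel P and
the KNN-restricted kernel S — enter the cross-view fusion iteration

    P⁽ᵛ⁾ ← S⁽ᵛ⁾ · ( Σ_{k≠v} P⁽ᵏ⁾ / (m−1) ) · (S⁽ᵛ⁾)ᵀ,

run for t rounds over all m views; the fused network is the across-view
average. Spectral clustering of the fused network (normalized Laplacian,
eigengap selection of k) yields the subtypes, which are scored by mean
silhouette width and the k-group log-rank test on survival.

A planted-truth synthetic cohort generator (`generate_cohort()`,
scenario *benchmark-v1*) emulates the target data regime — modular gene
network, Poisson-sparse mutations whose subtype signal is carried by module
membership rather than shared genes, noisy continuous layers,
subtype-dependent survival — so the whole pipeline is testable end to end
without external downloads.

## Worked example

```r
library(ndsnf)

co  <- generate_cohort(seed = 7)           # 100 patients, 3 planted subtypes
fit <- run_pipeline(co, snf_config(k_clusters = 3))
fit
#> <snf_fit> 100 patients, 4 view(s), mutation_mode = smoothed
#>   k = 3; mean silhouette = 0.114; log-rank p = 6.61e-05; ARI vs planted = 1
```

The three continuous layers and the diffusion-smoothed mutation layer fuse
into one network whose three blocks match the planted subtypes exactly
(adjusted Rand index 1); the subtypes separate survival strongly (log-rank
p = 6.6×10⁻⁵ across the three groups). Does the mutation layer need the
diffusion? Compare the three ways of using it:

```r
compare_methods(co, snf_config(k_clusters = 3))
#> # A tibble: 3 × 5
#>   method                 k mean_silhouette logrank_p   ari
#> 1 continuous             3          0.0774 0.0000661     1
#> 2 raw_mutations          3          0.0756 0.0000661     1
#> 3 smoothed_mutations     3          0.114  0.0000661     1
```

The smoothed-mutation pipeline yields the most coherent fused network
(highest mean silhouette); across 20 simulated cohorts its median subtype
recovery is at least as good as feeding the raw binary matrix through a
chi-squared kernel. Results objects have broom-style `tidy()`/`glance()`
methods and `autoplot()`/`plot_survival_curves()` displays; everything is
deterministic given the seed.

A thin command-line wrapper lives in `inst/scripts/ndsnf`
(`simulate`, `smooth`, `run`, `compare` subcommands).

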