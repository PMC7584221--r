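# dirclust

Bayesian directional multi-view clustering with asymmetric copulas.

## What problem this solves

Multi-omics cohorts measure the same samples on several platforms (gene
expression, DNA methylation, miRNA, protein arrays). A consensus clustering
of the samples should use all views at once — but the views are not
exchangeable: the central dogma gives the data types a *direction* (DNA →
mRNA → protein). Methods that assume independent or symmetric pairwise
dependence between views discard that structure. `dirclust` is for
biostatisticians who want an integrative clustering that encodes known
directional dependencies as a DAG over data types.

## The model

Each view `m` is a finite Dirichlet mixture with `K` components, weights
`γ_mk ~ Gamma(α_m/K, 1)`, and per-feature Normal likelihood under a
conjugate Normal–Inverse-Gamma base measure (component parameters
collapsed). The per-view allocations `L_mi` of sample `i` are coupled along
the directed edges `E` of the data-type graph:

    p(L_1i, …, L_Mi | γ, ρ) ∝ ∏_m γ_{m L_mi} · ∏_{(m,k)∈E} (1 + ρ_{m→k} 1{L_mi = L_ki})

Each coupling strength `ρ_{m→k} ≥ 0` carries a Gamma(1/2, rate) prior
derived from the Rodriguez-Lallena–Ubeda-Flores asymmetric copula
`C(u,v) = uv + ϑ·uv(1−u)^α(1−v)^β`: the asymmetry parameters are estimated
from the two views (Eq.-8-type closed-form estimators), the admissibility
bound `b` caps the association `ϑ ~ N(0, (b/3)²)`, and the induced law of
`ρ = c·ϑ²` with `c = 3α²β²/((2+α)²(1+2β))` is exactly the Gamma prior used.
Fitting is by an auxiliary-variable collapsed Gibbs sampler (`ξ → γ → ρ →
L` sweeps); the intractable normalizing constant and its derivatives are
computed exactly by an edge-subset expansion costing `O(2^|E| (K+M))`. The
consensus partition is the terminal (sink) view's clustering — the protein
view in an omics DAG.

The package also ships the asymmetric Tawn Type 1/2 and BB1 copulas with an
exact conditional-inversion sampler, directional-dependence estimators
(closed-form plug-in and a nonparametric copula-regression plug-in of
`12·E[r²] − 3`), a synthetic-data generator for copula-coupled
Gaussian-mixture views, posterior similarity matrices, and clustering
metrics (Hungarian-matched accuracy, Rand index).

## Worked example

```r
library(dirclust)

sc  <- simulation_scenario("true_direction", n = 500, seed = 1)
fit <- dirclust(sc$views, sc$graph, seed = 1)

glance(fit)
#> # A tibble: 1 × 8
#>       n views     K retained consensus_view clusters_modal clusters_mean mean_xi
#>   <int> <int> <dbl>    <int> <chr>                   <int>         <dbl>   <dbl>
#> 1   500     2   250     1000 U                           2          2.11    499.

tidy(fit)   # posterior of the directional coupling strengths
#> # A tibble: 1 × 7
#>   from  to    estimate std.error conf.low conf.high prior_rate
#>   <chr> <chr>    <dbl>     <dbl>    <dbl>     <dbl>      <dbl>
#> 1 V     U         74.4      11.5     53.8      97.4      0.349

clustering_accuracy(sc$labels, consensus_labels(fit))
#> [1] 0.982

rho_empirical(sc$scores$u, sc$scores$v, "v_to_u",
              as_pseudo = FALSE, method = "regression")$rho_hat
#> [1] 0.429
```

The scenario generates 500 samples in two views (two-component Gaussian
mixtures, means 0 and 3, sds 1 and 0.5) whose scores are coupled by a Tawn
Type 1 copula (ψ₁ = 0.5, θ = 30) with the V margin upstream, and hands the
model the true edge `V → U`. With `K = ⌈N/2⌉ = 250` available clusters the
sampler occupies 2 (the truth), the consensus accuracy 0.982 is at the
design's Bayes accuracy (≈ 0.978), the large posterior `ρ` says the views'
partitions agree essentially always, and the regression estimate 0.429 of
the V→U directional dependence matches the copula's true value 0.428.

`autoplot(fit)` draws the posterior similarity heatmap;
`reproduce_simulation()` replicates the three-condition experiment (true /
absent / reversed direction), the copula-family sweep and the sample-size
sweep, and `summarize_runs()` lays the results out per condition. A thin
command-line front end with `simulate` / `dependence` / `fit` / `evaluate`
/ `reproduce` subcommands is installed at `inst/cli/dirclust.R`.

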