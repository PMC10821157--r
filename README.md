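# lakeassembly

Statistical inference for amplicon surveys of lake microbial communities:
who is there, what drives them, and — the core question — **which
ecological processes assemble them**. The package quantifies the balance
of deterministic processes (environmental selection) and stochastic ones
(dispersal and drift) for bacterial and microeukaryotic communities
sampled across lake systems, and characterizes their co-occurrence
structure against random-graph expectations.

## What it computes

**Assembly processes** (the core):

* Sloan neutral community model — for a taxon with regional mean relative
  abundance *p*, drift plus immigration *m* into communities of *N<sub>T</sub>*
  individuals predicts occurrence frequency as the upper tail at
  *d* = 1/*N<sub>T</sub>* of Beta(*N<sub>T</sub>mp*, *N<sub>T</sub>m*(1−*p*));
  `fit_neutral()` estimates *m* and *R²* and partitions OTUs against a 95%
  Wilson band.
* betaMNTD / betaNTI — abundance-weighted mean nearest-taxon phylogenetic
  distance per sample pair, standardized against 999 tip-label shuffles
  (compiled null loop). |betaNTI| > 2 ⇒ selection (< −2 homogeneous,
  > 2 heterogeneous).
* RCbray — abundance-based Raup–Crick on Bray–Curtis with
  richness-and-abundance-conditioned nulls; > 0.95 ⇒ dispersal
  limitation, < −0.95 ⇒ homogenizing dispersal.
* `classify_processes()` — the strict five-way cascade over sample pairs,
  with per-process percentages, plus `bnti_env_correlation()` relating
  betaNTI to pairwise environmental differences (Δ pH, Δ DOC, ...).

**Around it**: alpha diversity (Shannon, Simpson, Chao1, Pielou, Faith's
PD), Bray–Curtis + PCoA + ANOSIM, Kruskal–Wallis / Mann–Whitney group
tests, Spearman screens with BH stars, VIF-screened RDA with marginal
permutation tests, PCNM spatial eigenfunctions, adjusted-R² variation
partitioning, Spearman co-occurrence networks (|ρ| > 0.8, BH-adjusted
p < 0.01) with topology and 1000-replicate Erdős–Rényi ensembles, and a
synthetic metacommunity generator with five controllable assembly regimes
and recorded ground truth.

Everything takes tibbles and returns tibbles; fitted objects have
`tidy()` / `glance()` / `autoplot()` methods; `run_pipeline()` chains all
stages into a deterministic TSV bundle.

## Worked example

Simulate a 4-lake survey under homogeneous selection and ask the package
which process assembled it:

```r
library(lakeassembly)

cfg <- sim_config(n_groups = 4, samples_per_group = 4, n_taxa = 2000,
                  regime = "homogeneous_selection", m = 0.005,
                  library_size = 10000, seed = 1)
sim <- simulate_metacommunity(cfg)

alpha_diversity(sim$community, sim$tree)
#> # A tibble: 16 × 8
#>   sample group richness shannon simpson chao1 pielou faith_pd
#>   <chr>  <chr>    <int>   <dbl>   <dbl> <dbl>  <dbl>    <dbl>
#> 1 L1_S01 L1         267    3.77   0.963 1869.  0.675     557.
#> 2 L1_S02 L1         255    3.77   0.965 1380.  0.680     516.
#> ...

glance(fit_neutral(sim$community))
#> # A tibble: 1 × 8
#>       m    r2   N_T n_samples n_otus frac_above frac_within frac_below
#>   <dbl> <dbl> <dbl>     <int>  <int>      <dbl>       <dbl>      <dbl>
#> 1 0.434 0.603 10000        16   1608    0.00311       0.974      0.0230

bnti <- beta_nti(sim$community, sim$tree, n_null = 199, seed = 1)
rc   <- raup_crick(sim$community, n_null = 199, seed = 1)
classify_processes(bnti, rc)
#> Assembly process classification over 120 sample pairs
#> # A tibble: 5 × 3
#>   process                     n percent
#>   <chr>                   <int>   <dbl>
#> 1 homogeneous_selection      92   76.7
#> 2 heterogeneous_selection     0    0
#> 3 dispersal_limitation       24   20
#> 4 homogeneous_dispersal       0    0
#> 5 undominated                 4    3.33
```

The classification recovers the generating regime: 76.7% of pairs fall to
homogeneous selection (betaNTI < −2). Note the neutral fit's *R²* = 0.60
despite the data being selection-dominated — occupancy–abundance curves
alone discriminate assembly processes poorly, which is exactly why the
null-model stack exists. Under a genuinely neutral regime
(`regime = "neutral"`, m = 0.1) the same fit recovers m within a few
percent with *R²* ≈ 0.98.

`autoplot()` on the neutral fit draws the occupancy–abundance curve with
its confidence band; `autoplot()` on the classification result draws the
stacked process bar; `plot_pcoa()` and `autoplot()` on networks cover the
ordination and graph views.

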