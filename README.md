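# antnets

Multilayer analysis of ant–plant interaction networks in R.

Foliage-dwelling ants interact with plants through several kinds of
plant-derived food at once — extrafloral nectar (EFN), floral nectar and
pollen, fruit pulp, and honeydew from tended hemipterans (trophobionts) —
plus plain visits without observed feeding. Studying one interaction type at
a time hides how these layers fit together. `antnets` is for community
ecologists who record interaction *events* in the field (one row per
observation: site, plot, season, plant species, ant species, resource type,
worker count) and want to ask, with proper null models:

* How specialized, nested and modular is each resource layer, and the pooled
  multilayer network?
* Do layers built on different resources differ in structure?
* Is the core of highly connected species the *same* set of species across
  layers?

## Methods at the core

All layers are weighted bipartite matrices `A` (plants × ants, cell `a_ij` =
number of events), with margins `r_i`, `c_j` and total `F`.

* **Complementary specialization H2′** — two-dimensional Shannon entropy
  `H2 = −Σ p_ij ln p_ij` (with `p_ij = a_ij/F`) rescaled between the
  margin-constrained extremes: `H2′ = (H2max − H2)/(H2max − H2min)`;
  0 = interactions at the independence expectation, 1 = maximal
  specialization. Bounds are exact (enumeration) for tiny matrices and use
  greedy heuristic fills otherwise.
* **Weighted nestedness WNODF** — mean over ordered row and column pairs of
  `100 · #{k : 0 < a_jk < a_ik} / #{k : a_jk > 0}`, counted only where
  margin totals strictly decrease.
* **Morisita–Horn niche overlap** — mean over guild pairs of
  `C = 2 Σ p q / (Σ p² + Σ q²)` on relative-use vectors.
* **Weighted bipartite modularity** —
  `Q = Σ_ij (a_ij/F − r_i c_j/F²) δ(m_i, m_j)`, maximised by simulated
  annealing (reassign / merge / split moves, geometric cooling) with
  best-of-N restarts; significance as standardized Q, the number of null
  standard deviations above the mean Q of fixed-margin randomizations.
* **Null models and tests** — Patefield fixed-margin sampling
  (`stats::r2dtable`) with pseudocount Monte-Carlo p-values
  `(1 + #extreme)/(N + 1)`; pairwise layer differences tested against paired
  independent null draws; per-site descriptors compared by Poisson GLM;
  core composition (species with degree above the network mean) compared
  across layers by PERMANOVA on Jaccard distances and ordinated by NMDS.

A synthetic community generator (`generate_events()`) emulates the sampling
design these methods were built for — 7 sites, 78 plant and 30 ant species,
795 events dominated by visits, a strongly skewed ant abundance
distribution, a small shared core of generalist ants, and largely distinct
plant subsets carrying each reward layer — with full ground truth for
testing and calibration.

## Worked example

```r
library(antnets)

g  <- generate_events(generator_config(seed = 42))  # synthetic field season
ml <- build_multilayer(g$events)
ml
#> <multilayer_network>
#>   EFN           22 plants x 21 ants  F=172
#>   flower        21 plants x 10 ants  F=70
#>   fruit          2 plants x  3 ants  F=3
#>   trophobiont   13 plants x  6 ants  F=37
#>   visit         75 plants x 29 ants  F=513
#>   pooled        76 plants x 30 ants  F=795

metric_significance(ml$layers$EFN, wnodf, n_null = 99, "greater", seed = 1)
#> <metric_report> observed = 33.6602  null = 28.6213 +/- 2.6914  P = 0.06 (greater, N = 99)

best_of(ml$layers$EFN, n_iter = 20, seed = 2)
#> <module_partition> Q = 0.2798  modules = 4  species = 43

cores <- site_cores(g$events)
core_similarity_permanova(cores, "ants",   n_perm = 999, seed = 3)
#> <permanova_result> pseudo-F(2, 12) = 0.545  R2 = 0.083  p = 0.689 (n = 15, 999 permutations)
core_similarity_permanova(cores, "plants", n_perm = 999, seed = 4)
#> <permanova_result> pseudo-F(2, 9) = 2.253  R2 = 0.334  p = 0.001 (n = 12, 999 permutations)
```

The EFN layer is moderately nested relative to its fixed-margin null
(observed WNODF 33.7 vs 28.6 ± 2.7 expected; one-sided P = 0.06) and splits
into four modules at Q = 0.28. The core comparison shows the planted
contrast: the identity of core *ants* is statistically indistinguishable
across resource layers (P = 0.689), while core *plants* differ sharply
(P = 0.001) — the same qualitative pattern the pipeline is designed to
detect in real data.

`run_pipeline(events, pipeline_config(...), out_dir = "results/")` chains
every step above (per-layer metrics with significance, pairwise layer
comparisons, descriptor GLMs, cores, PERMANOVA, NMDS) and writes
`report.json` plus CSV tables; the whole run is a pure function of
`(events, config, seed)`.

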