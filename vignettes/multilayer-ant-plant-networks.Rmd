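---
title: "Methods: multilayer ant-plant network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilayer ant-plant network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antnets)
```

## The data model

The atomic observation is an interaction *event*: one record of an ant
feeding on (or visiting) a plant, with site, plot, season, resource type and
the number of recruited workers. Interaction frequency between a plant and
an ant is the number of such events, not the worker count — workers are kept
as recruitment metadata only. The five resource categories form a closed
vocabulary (`r paste(resource_types(), collapse = ", ")`); anything else is
rejected at parse time so silent typos cannot leak into matrices.

`build_layer()` tabulates events into a weighted bipartite plant × ant
matrix per resource type; `build_multilayer()` adds the pooled matrix, the
element-wise sum of all five layers (visits included), so the pooled total
always equals the number of events. Species absent from a layer are dropped
— no all-zero row or column survives construction — and species are ordered
lexicographically (C-locale radix sort), which makes every downstream
stochastic procedure reproducible from a seed regardless of input row order.
Site pooling happens before species dropping: per-site matrices are built
only for the descriptor and core analyses.

## Network metrics

**Complementary specialization H2′.** With `p_ij = a_ij / F`, the
two-dimensional entropy `H2 = -sum(p_ij log p_ij)` is rescaled between the
minimum and maximum entropies attainable by non-negative *integer* matrices
with the observed margins: `H2' = (H2max - H2) / (H2max - H2min)`. The
bounds are computed exactly, by enumerating all tables with those margins,
when the total is at most 12 *and* the matrix has at most 16 cells; the cell
cap is a feasibility guard (a 12 × 12 matrix of all-ones margins would
otherwise require enumerating 12! tables). Beyond that the package uses
greedy heuristic fills: for `H2max`, units are allocated one at a time to
the feasible cell farthest below its independence expectation
`r_i c_j / F`; for `H2min`, mass is repeatedly concentrated by placing
`min(max remaining row, max remaining column)` into the cell joining those
margins. On pathological margins the heuristic bounds can differ slightly
from the exact optima, which is why the scale-invariance of H2′ under
integer rescaling holds exactly in the enumeration regime and only to ~1e-2
across regimes. If `H2max = H2min` (margins force a unique entropy) the
index is defined as 0.

**WNODF.** Rows are sorted by decreasing totals (ties keep label order, so
tied margins contribute zero via the strict decreasing-fill condition),
columns likewise; an ordered pair contributes
`100 * #{k : 0 < a_jk < a_ik} / #{k : a_jk > 0}` when totals strictly
decrease and 0 otherwise, and WNODF is the mean over all row and column
pairs.

**Morisita-Horn overlap** is the unweighted mean of the pairwise index over
all guild pairs (columns for ants). The entropy-based Horn variant is *not*
used; the implemented formula is `2 sum(pq) / (sum(p^2) + sum(q^2))` on
relative-use vectors, and results are labelled accordingly.

**Degree** is binary (number of distinct partners), not interaction
strength; it feeds both the degree-sum invariants and the core rule.

## Modularity

The quality function is the weighted bipartite (Barber-type) modularity
`Q = sum_ij (a_ij/F - r_i c_j/F^2) delta(m_i, m_j)`, evaluated over
plant-ant pairs only; the all-in-one partition scores exactly 0.
Maximisation is by simulated annealing in compiled code: every species
starts in its own module, and moves either reassign one species (to an
existing or fresh module), merge two modules, or split one module by a
random bipartition. The schedule is geometric: initial temperature
`0.02 * F`, cooling factor 0.99 per move, stopping after `50 * S` moves
without improvement (S = species count) with a hard cap of 2e5 moves. These
schedule constants are exposed in `quanbimo_config()`. The best partition
*visited* is returned, and if its Q is negative the trivial single-module
partition (Q = 0) is returned instead, so a fitted Q is never below the
trivial baseline. `best_of()` repeats the search with restart seeds spawned
deterministically from one master seed, so the best-of value is monotone
non-decreasing in the number of restarts for a fixed master seed. The
published description of this algorithm speaks of "iterations"; we read
that as independent restarts (consistent with retaining the optimum over
repeated runs), and the restart count is a plain argument everywhere.

Significance of modularity is reported as *standardized Q*: how many null
standard deviations the observed (best-of) Q sits above the mean best-of Q
of fixed-margin randomizations, flagged significant at 2 or more. The flag
is one-sided by design: a structureless matrix has observed Q = 0 while
nulls carry positive sampling-noise modularity, so z is typically negative
there — a large negative z is not evidence of structure. If every null draw
yields the same Q (margins that force a unique optimum) the null SD
collapses and the result is flagged degenerate rather than given an
arbitrary z.

## Null models and resampling tests

All randomizations are fixed-margin (Patefield) draws from the
independence-conditional distribution, delegated to `stats::r2dtable`
(single-row or single-column margins, which that sampler rejects, are
forced tables and handled directly). Every p-value uses the pseudocount
convention `(1 + #extreme)/(N + 1)`, so p is never exactly 0; two-sided
extremeness is distance from the null mean. Null draws on which a metric is
undefined are excluded and counted in the report.

The pairwise layer comparison randomizes *each layer with its own
fixed-margin null* and differences the metric on paired draws. The field
protocol behind this test does not say what was resampled; cell-level
randomization is the only null machinery its methods introduce, so that is
what is implemented (a site-level permutation scheme would be an
alternative reading; it is noted here and not implemented). The fruit layer
is excluded from comparisons by default — it is typically too small for the
metrics to be comparable — behind an `include_fruit` flag.

## Descriptors, cores, PERMANOVA, NMDS

Per-site, per-resource descriptors are network size (interacting species),
richness (distinct pairs) and frequency (events); resource-type effects are
tested by log-link Poisson GLM against the intercept-only model
(chi-squared analysis of deviance). Core species are those with degree
*strictly greater* than the network-average degree; the threshold pools
plants and ants by default (the field description does not say whether the
average was pooled or per guild; `per_guild = TRUE` gives the other
reading). Core composition per (site, resource) is a presence/absence
incidence table; sites whose core is empty for a guild carry no composition
and are dropped with a logged count.

PERMANOVA is implemented directly (Anderson's partitioning of squared
distances; `R2 = SS_between / SS_total`; free permutation of observations)
rather than delegated, because the implementation must also accept an
explicit permutation matrix for exhaustive enumeration at tiny n — the test
suite cross-checks pseudo-F and R² against `vegan::adonis2` and the
Monte-Carlo p against full enumeration. Distances are Jaccard on
presence/absence by default (cores are sets); Bray-Curtis on
degree-weighted incidence is available behind a flag. Note the resolution
limit of free permutation: with two groups of three observations the
smallest attainable p is about 0.10, so "significant dissimilarity" is
simply not reachable at that design size.

NMDS minimises Kruskal stress-1 via `vegan::monoMDS` (global model,
primary/averaged tie treatment) over one classical-scaling start plus
random starts; the best solution is centered. All-zero distance matrices
are reported as degenerate rather than ordinated.

## The synthetic community generator

`generate_events()` emulates the study design the pipeline targets: 7
sites, 78 plant and 30 ant species, 795 events split roughly 66% visits,
20% EFN, 8% flower, 5% trophobiont, 1% fruit. Within that frame it plants
recoverable structure:

* **Abundance skew.** Species weights are log-normal (sigma = 0.8), and
  the 3 core ants get a 4-fold boost; the defaults reproduce a community
  where the top ant takes roughly a third of all records and the top five
  take three quarters.
* **Specialization knob.** Pair propensity is damped by a Gaussian kernel
  on latent uniform traits whose *inverse bandwidth* is
  `specialization * layer multiplier`; the exponent is
  `((spec * mult)^2 / 2) * (trait_p - trait_a)^2`. Below roughly
  `specialization = 2` the bandwidth exceeds the trait range and the kernel
  is effectively flat, so recovery experiments sweep the operating range
  (about 4-40). As specialization grows without bound each plant collapses
  onto a single best-matching partner and pooled H2′ approaches 1. Layer
  multipliers (visit 0.5 < EFN 1 < flower = fruit 2 < trophobiont 4) order
  the layers from a weakly specialized visit background to a strongly
  specialized trophobiont layer.
* **Shared ant core.** Core ants keep only `core_matching = 0.1` of the
  inverse bandwidth — they are massively recruiting generalists, the
  mechanism proposed for real core ants — so the same three species stay
  central in every layer at every site.
* **Distinct plant layers.** Each plant offers each reward with a fixed
  probability (EFN 0.22, flower 0.29, trophobiont 0.23, fruit 0.05; visits
  reach everyone), and each reward layer additionally has its own 6 boosted
  core plants, disjoint across layers by default. Together these make core
  *plant* composition differ across layers while core *ant* composition
  does not — the contrast the community-level tests are meant to detect.
* **Sites.** Site weights are Gamma-distributed and each plant occurs at a
  site with probability 0.7, so site-level networks differ realistically in
  size and composition. The fruit layer is restricted to 4 ant species to
  exercise the sparse-layer code paths.

Events are a single multinomial allocation of the total over (site, plant,
ant, resource) propensities, with each layer's mass normalized before
mixing so realized layer shares follow `layer_mix`. Worker counts are
`1 + geometric`, inflated for core ants.

What the generator does *not* emulate: seasonal phenology (the season field
is uniform noise), observation effort differences between campaigns,
spatial autocorrelation among plots, taxonomic structure, and
trophobiont-species resolution (the trophobiont layer is generated, like
the others, as plant × ant). Passing tests on synthetic data therefore
demonstrate correctness and calibration of the *methods*, not that any
particular field system matches the generator's mechanism. Two planted-
matrix helpers (`planted_modular_matrix`, `planted_nested_matrix`) provide
sharper single-property fixtures for modularity and nestedness.

Note also that the default synthetic community is *less* modular than a
typical field community: the flat-kernel core ants cut across any module
structure, so standardized Q on default synthetic runs is usually
unremarkable. Planting modules (`n_planted_modules`) restores strong,
detectable modularity.

## Numerical and design choices

* Pseudocount p-values; two-sided extremeness as distance from the null
  mean; equality tolerances of 1e-12 in all tail counts.
* Margin-sorting ties in WNODF keep original label order and contribute 0.
* The H2′ exact/heuristic switch is total ≤ 12 *and* ≤ 16 cells.
* Annealing seeds: one master seed spawns child seeds via the R RNG; all
  compiled code draws through R's RNG so `set.seed` governs everything.
* Degenerate inputs are signalled, not silently absorbed: empty layers,
  single-row/column metrics, zero-SD modularity nulls, all-zero distance
  matrices and all-empty core designs each raise a classed condition.
* Routine problem sizes: the test suite runs metric oracles exhaustively on
  all matrices up to 3 × 3 with total ≤ 6, annealing-vs-enumeration on
  4 × 4 fixtures, type-I calibration on 500 paired 6 × 5 null draws at 199
  randomizations, recovery experiments at the generator's default scale,
  and end-to-end pipeline runs at reduced null counts
  (`pipeline_config(fast = TRUE)`: 99 metric nulls, 50 modularity nulls, 3
  restarts). Full-protocol settings (999/1000/1000) remain the documented
  defaults of `pipeline_config()`.

## Known limitations

* Heuristic H2′ bounds are approximations; on adversarial margins H2′ can
  shift by a few hundredths relative to exact enumeration.
* The annealer is stochastic; with very few restarts on large matrices the
  reported Q is a lower bound on the optimum. Restart counts trade time for
  tightness explicitly.
* PERMANOVA uses free permutation only; restricted (within-site) permutation
  schemes are not implemented.
* The pairwise layer test conditions on layer margins; it does not model
  shared sampling between layers (events are allocated to exactly one
  layer, so layers are dependent in real data in ways the null ignores).
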