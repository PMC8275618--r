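# qicd — quantum-inspired community detection for biodiversity change networks

`qicd` asks a species-distribution question with network tools: which groups
of administrative units move together in population growth of a focal
species, and do those groups track land-use and climate drivers? The worked
system is the tiger population of 18 Indian states across the 2010/2014/2018
censuses. Units become nodes; *intra-links* connect units in the same
growth-rate subgroup (binned percentage population increase between the first
two censuses); *inter-links* connect units sharing an attribute class, giving
two benchmark networks:

* **landscape network** — inter-links within each of 4 geographical landscape
  classes;
* **reserves network** — inter-links within the two classes of a
  reserve-count split (3 or more tiger reserves versus fewer).

Communities are then detected with three quantum-inspired optimizers and a
native Girvan–Newman baseline, scored with standard partition metrics, and
correlated with per-community driver aggregates.

## Methods at a glance

* **Modularity** (the objective everywhere):
  `Q = Σ_i (e_ii − a_i²)`, with `e_ii` the fraction of edges inside community
  `i` and `a_i` the fraction of edge endpoints in `i`.
* **binQIEA** — qubit chromosomes `|Ψ⟩ = α₁|0⟩ + α₂|1⟩`, `|α₁|² + |α₂|² = 1`,
  one gene per node; measurement collapse, modularity evaluation, rotation
  toward the best observation, wrapped in hierarchical bi-partitioning.
* **numQIEA** — per-node amplitude vectors over neighbors (locus-based
  adjacency encoding); decoding is connected components of the pointer graph,
  so the community count emerges dynamically.
* **QDMPSO** — quantum-behaved discrete particle swarm over label vectors
  with a personal/global-best attractor and a delta-well jump; optional
  bi-criteria mode (intra-community density vs inter-community link
  fraction) resolved by fast non-dominated sorting.
* **Mixing parameter µ** — per-gene random-exploration probability per
  generation, swept over `{0, 0.05, …, 0.5}` with repeated restarts.
* **Driver correlation** — Pearson's r between per-community aggregates
  across census timestamps/intervals, with the exact two-tailed
  `t = r√(n−2)/√(1−r²)` test at `df = n − 2`.

## Worked example

```r
library(qicd)

fx <- tiger_fixture()                      # packaged synthetic reconstruction
g  <- build_network(fx$counts, fx$attributes, "reserves")
igraph::ecount(g)
#> [1] 85

gn <- girvan_newman(g, target_k = 4)
gn
#> <qicd_gn> Girvan-Newman on 'reserves': 2 communities at max Q = 0.3471

head(node_centrality(g), 3)
#> # A tibble: 3 × 4
#>   unit_id        degree degree_centrality_norm betweenness
#>   <chr>           <int>                  <dbl>       <dbl>
#> 1 Uttar Pradesh      12                  0.706        21
#> 2 Andhra Pradesh     11                  0.647         7
#> 3 Chhattisgarh       11                  0.647        15.6

fit <- run_qdmpso(g, qicd_config(seed = 7, generations = 60))
glance(fit)
#> # A tibble: 1 × 5
#>   algorithm graph    modularity n_communities  seed
#>   <chr>     <chr>         <dbl>         <int> <int>
#> 1 qdmpso    reserves      0.347             2     7

correlate_drivers(fx$attributes, gn$partition_at_k, "reserves")
#> # A tibble: 2 × 7
#>   dataset  variable               pair  statistic     r     p     n
#>   <chr>    <chr>                  <chr> <chr>     <dbl> <dbl> <int>
#> 1 reserves reserve_count          I2I1  sum       0.494 0.506     4
#> 2 reserves core_area_pct_increase I2I1  mean      0.287 0.713     4
```

The modularity 0.347 means roughly a third more of the network's edges fall
inside the detected communities than a degree-matched random graph would
place there; the maximum degree of 12 marks Uttar Pradesh as the most
connected state under the reserve-count wiring. The correlation rows pair the
2010–2014 and 2014–2018 per-community aggregates of reserve additions (summed)
and core-area growth (averaged); with only `n = 4` communities each r is
fragile, which is why `n` is always reported alongside.

Synthetic studies with known structure come from the generator:

```r
spec   <- synthetic_spec(n_units = 18, seed = 1)
counts <- generate_species_counts(spec)
attrs  <- generate_attributes(counts, spec)
res    <- run_pipeline(counts, attrs, out_dir = "out")
```

The packaged fixture is a *synthetic reconstruction* assembled from publicly
available census and reserve figures (see `?tiger_fixture`); it reproduces
the study design — 18 units, 4 landscape classes, a two-class reserve split —
not any previously printed statistic.

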