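---
title: "Quantum-inspired community detection for biodiversity change networks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-inspired community detection for biodiversity change networks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package treats biodiversity change as a network problem. Administrative
units (Indian states harboring tiger reserves) are nodes. Two families of
edges encode the study design:

* **intra-links** connect units in the same *growth subgroup*, obtained by
  binning the percentage population increase between the first two censuses,
  `100 (n_t1 − n_t0) / n_t0`, into (by default) four equal-count quantile
  groups;
* **inter-links** connect units sharing an attribute class: one of four
  geographical landscape classes (the *landscape network*) or one of the two
  classes of a reserve-count threshold split at 3 reserves (the *reserves
  network*).

Each subgroup is wired as a clique by default, and the network is the
deduplicated union of the two edge families — simple, undirected, unweighted.
The clique rule is the only parameter-free choice and reproduces a maximum
degree of 12 on 18 nodes for the reconstruction shipped with the package; a
ring and a star rule are available through the `rule` argument because the
wiring of the original supplementary tables is not published. One arithmetic
consequence worth recording: under clique wiring any two-class split of 18
units contributes at least `C(9,2)·2 = 72` inter-link edges by itself, so
clique-wired reserves networks are necessarily denser than some published
edge counts for comparable designs; direct edge-list ingestion
(`read_edge_list()`) is the escape hatch when an exact wiring is available.

Community quality is Newman–Girvan modularity,
`Q = Σ_i (e_ii − a_i²)`,
computed by the package's own implementation (`modularity_q()`), which the
test suite checks against direct summation and against igraph on random
graphs.

## The three quantum-inspired optimizers

**binQIEA.** A chromosome holds one qubit per node, the amplitude pair
`(α₁, α₂)` with `α₁² + α₂² = 1`; `α₂²` is the probability that measurement
collapses the gene to 1. A population of chromosomes is repeatedly collapsed,
each observation scored by global modularity, and every gene rotated toward
the best observation by the standard lookup: zero angle where the collapsed
and best bits agree, `±θ₁` toward the best bit where they disagree (and `±θ₂`
back toward the observed bit in the tie case where the observation is not
worse). Rotation is orthogonal, so normalization is exact by construction;
angles are clamped to `[0, π/2]` to keep amplitudes in the first quadrant.
Because a chromosome encodes one bipartition side per node, binQIEA is
wrapped in hierarchical bi-partitioning: starting from a single community,
each community is offered to the bipartition routine and a split is kept only
if it strictly raises global Q, recursing to `max_depth` levels. The best
split found by the evolutionary loop is polished by single-bit hill climbing
before acceptance — binQIEA is a local-search modularity maximizer, and
without this step greedy bi-partitioning can stall one node short of a
planted optimum.

**numQIEA.** The real-coded variant keeps, for every node, an amplitude
vector over the node's neighbors (a generalized qubit per locus). Observation
samples one neighbor per node; the decoded partition is the connected
components of the resulting pointer graph, so the number of communities
emerges dynamically rather than by recursive splitting. Amplitudes rotate
toward the best observation's neighbor choice; with probability µ a locus
re-initializes to the uniform superposition.

**QDMPSO.** Particles are community label vectors. Each dimension follows a
discrete local attractor — the personal best with probability `alpha_coef`,
otherwise the global best — and, where the particle has not yet collapsed
onto its attractor, performs a delta-well jump (adopting a random neighbor's
current label) with probability proportional to the contraction–expansion
coefficient `β`, which decreases linearly from `beta_coef` to `beta_coef/2`
across generations. A converged swarm is a fixed point by construction, and
the elitist global best makes the modularity trace non-decreasing. The
optional bi-criteria mode scores every evaluated particle on mean
intra-community edge density (maximized) and inter-community link fraction
(minimized), extracts the first front by fast non-dominated sorting, and
returns the front's maximum-modularity member.

All three algorithms share the µ semantics (per-gene random
re-initialization each generation), a strict-improvement acceptance rule, and
a final greedy single-node relabeling refinement of the returned partition.
The refinement is a deliberate design choice: the package's contract is that
the best of repeated runs on small graphs equals the exhaustive-search
modularity maximum (verified against full set-partition enumeration in the
tests), and the raw evolutionary loops alone do not reliably deliver that.
Its side effect is that the three algorithms converge to very similar peaks
on 18-node networks, so differences between them show up in the mean and
spread of the sweep rather than the maximum.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `population_size` | 20 | chromosomes / particles per generation |
| `generations` | 100 | cap per evolutionary loop (early stopping below) |
| `mu` | 0.1 | per-gene exploration probability, swept over `{0,…,0.5}` |
| `theta1`, `theta2` | `0.01π`, `0.025π` | rotation-gate magnitudes (radians) |
| `alpha_coef` | 0.75 | QDMPSO attractor weight toward the personal best |
| `beta_coef` | 1.0 | QDMPSO contraction–expansion start value |
| `runs` | 40 | restarts per µ value in the sweep |
| `max_depth` | 4 | hierarchical bipartition levels (supports 4 communities) |
| `patience` | 15 | generations without improvement before stopping |

The rotation angles and swarm coefficients are conventional magnitudes for
this algorithm family; because no canonical values exist, `tune_parameters()`
runs a small NSGA-II (fast non-dominated sort, crowding distance, binary
tournament, blend crossover, Gaussian mutation) over
`(θ₁, θ₂, alpha_coef, beta_coef)` with objectives *maximize mean Q* and
*minimize its SD* over repeated runs, returning the knee point of the final
front. The default configuration is seeded into the initial population, so
tuning can never end below it on the same evaluation protocol.

µ deserves a note: for fixed real-world networks a "mixing parameter" cannot
be the synthetic-benchmark generation parameter of the same name, so the
package reads it as the exploration/exploitation mix — the probability per
gene and generation of random re-initialization. This is the only reading
under which sweeping µ on a fixed graph is meaningful.

Analyses in the test suite and the acceptance script run with
`generations = 60` and `patience = 10`: on 18-node networks the loops
converge well before 60 generations, and the early-stopping patience, not the
cap, is what binds. Determinism is end-to-end: a master seed spawns per-run
seeds through a documented counter scheme (`derive_seed()`), so any sweep
cell can be replayed in isolation.

## Baseline and metrics

The native Girvan–Newman implementation removes the maximum
edge-betweenness edge (recomputed each step; ties broken by lexicographic
edge id for determinism), tracking components and modularity after every
removal. Both cuts are reported: the global maximum-Q partition and, when
`target_k` is given, the first partition reaching that community count —
because a fixed four-community reading of a dendrogram and a max-Q reading
are both defensible and they can disagree. Betweenness itself, degree, and
components are delegated to igraph; the suite checks the package's
betweenness surface against a brute-force all-shortest-paths enumeration on
small graphs. NMI uses the arithmetic-mean entropy normalization (max-entropy
variant by flag), with the zero-entropy convention: 1 if both partitions are
the identical single block, else 0. ARI is the usual pair-counting form,
cross-checked against an independent implementation. The five non-native
baselines in `run_standard_suite()` (label propagation, Louvain, CNM, leading
eigenvector, walktrap, fast edge-betweenness) are igraph routines; their
partitions are rescored with the package's own modularity so all columns are
comparable.

## Driver correlations

Detected communities are linked to drivers by aggregating each driver series
per community — means for temperature/precipitation anomalies and core-area
percentage increase, sums for reserve counts — and correlating aggregate
vectors across census timestamps (landscape: the three pairs of 2010/2014/
2018) or intervals (reserves: 2010–2014 vs 2014–2018). Significance uses the
exact small-sample transform `t = r√(n−2)/√(1−r²)` with `df = n − 2`,
two-tailed; with four communities `df = 2`, which is why every result carries
`n` and the module refuses `n < 3`. The attribute table therefore carries
per-interval reserve additions (`reserve_count_interval_1/2`) alongside the
total `reserve_count` used for the class split, and the core-area columns
hold the per-interval average percentage increase — the quantities actually
correlated.

## The synthetic generator

`synthetic_spec()` encodes the study conditions: units split into
`n_growth_groups` growth subgroups (default 4) with Gaussian noise around
group mean growth rates; an independent uniform 4-class landscape attribute;
reserve counts drawn so a configurable fraction clears the threshold of 3;
and driver series whose *community-aggregated* values equal
`base + driver_effect · (rank − 1) + N(0, driver_noise_sd)` exactly, with
unit-level jitter centered within each group. The association is injected at
the aggregate level because that is the level at which the analysis
correlates drivers. Baseline counts are multiples of 100 so that integer
group means with zero noise reproduce the target percentage increases
exactly, which makes the generator self-verifying. What the generator does
*not* emulate: spatial autocorrelation between neighboring states, census
measurement error, attribute–growth confounding, and temporal driver trends
beyond a per-timestamp base shift. Tests passing on synthetic data therefore
demonstrate correctness of the machinery under the declared statistical
structure, not robustness to real-data violations of it.

## The packaged fixture

The shipped 18-state tables (`tiger_fixture()`) are a synthetic
reconstruction assembled from publicly available census and reserve figures:
2010/2014/2018 census counts, landscape complex membership, reserve counts
with their per-interval additions, and plausible anomaly values. The files
are named `*_synthetic.csv` and marked as such because the original study's
supplementary tables are not publicly deposited. Analyses on the fixture
reproduce the design (18 nodes, four landscape classes, a two-class reserve
split, a maximum degree of 12 held by Uttar Pradesh on the reserves network)
— not previously printed partition statistics, which depend on the exact
unpublished wiring.

## Numerical choices and degenerate inputs

* Community ids are 1-based, contiguous, canonicalized by first appearance —
  the lexicographically smallest equivalent labeling, which is also the
  tie-break between equal-Q candidates.
* Strict improvement thresholds use `1e-12`; qubit normalization is enforced
  at `1e-9` on input and is exact after rotation.
* Graphs with no edges or fewer than two nodes are rejected (`Q` undefined);
  all-equal growth values make quantile grouping degenerate and raise an
  error rather than returning arbitrary bins.
* Zero-variance vectors are rejected by `pearson_r()`; `|r| = 1` is rejected
  by the p-value transform.

## Known limitations

* With 18 nodes and dense clique wiring, the modularity landscape is shallow;
  all three optimizers (and good baselines) typically find the same global
  optimum, so the sweep's maximum is insensitive to µ and algorithm — the
  informative columns are the mean and SD.
* Four-point correlations have `df = 2`: confidence in any single r is low by
  construction, and the package deliberately reports rather than hides this.
* The bi-criteria QDMPSO mode keeps the evaluation archive in memory; it is
  intended for desk-scale networks, not large graphs.
* No weighted, directed, temporal, bipartite, or overlapping-community
  variants.
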