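---
title: "netprior: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netprior: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models and
procedures, the parameters that matter, what the synthetic generator
emulates, the numerical choices, and the places where the design was
genuinely open and a decision had to be made. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Evidence-seeded propagation and the priority rating

Per-gene genetic evidence arrives in named non-negative layers — canonically
*nGene* (genomic proximity to associated variants), *eGene* (expression-QTL
support) and *cGene* (promoter-interaction support). `combine_evidence()`
takes a weighted sum (default weights all 1; no published combination scheme
exists for this construction, so the simplest symmetric choice is pinned)
and normalizes it to a probability vector. All-zero evidence degenerates to
the uniform vector, so downstream propagation then reports pure network
centrality rather than failing.

`propagate()` runs the canonical random walk with restart,

  p ← (1 − r) · W · p + r · p₀,

with `W` the column-normalized adjacency. Power iteration stops when the L1
change drops below `tol` (default 1e-10) or at `max_iter` (default 10,000;
hitting the cap sets a warning flag rather than erroring, so long-running
batch analyses keep their partial answer). Mass is conserved at every step,
so the affinity is itself a probability vector. Disconnected inputs are
handled by construction: each component keeps exactly the seed mass it
started with, and isolated nodes retain their seeds untouched.

The restart probability defaults to **r = 0.75** — a conservative value that
keeps affinities close to the genetic evidence and uses the network mainly
to break ties among comparably supported genes. Smaller r diffuses further
but, on scale-free networks, increasingly rewards hubs (the walk's
stationary distribution without restart is degree-proportional); see §7.

`rate_genes()` maps affinity to the bounded 0–5 **priority rating** by the
rank transform `5(N − rank + 1)/N` with average ranks for ties. The rating
is deliberately rank-based, not affinity-proportional: the published rating
scale is bounded 0–5 and its internal transform is not public, so a uniform
rank map is the assumption-free stand-in. Comparisons to any published
numeric ratings are therefore out of scope. The integer `rank` column breaks
ties by gene symbol so that `top_fraction()` cut-offs are deterministic;
fraction-to-count conversion rounds half away from zero (top 1% of 12,466
genes = 125).

## 2. Enrichment

`fisher_enrichment()` is the one-sided (greater) Fisher test computed as the
hypergeometric upper tail `P(X ≥ k)`; gene sets are intersected with the
declared universe first, and query genes outside the universe are an error
because silently dropping them would bias the query size. The odds ratio is
the 2×2 cross-product with Haldane's 0.5 correction when any cell is zero;
the 95% CI comes from the log-OR normal approximation; the z-score
standardizes `k` by the hypergeometric mean and standard deviation (the
historical "enrichment Z" has no fixed published definition, so the
hypergeometric standardization is adopted and documented). FDR is
Benjamini–Hochberg across the collection; the step-up with monotone
enforcement guarantees FDR ≥ p per set, which the suite asserts.

The universe default for pathway prioritization is the prioritized-gene
universe (all genes that received a rating) — the choice consistent with
reconstructing printed contingency examples. Query defaults: top 2% of
ratings for pathway prioritization, top 1% for neighbour-set analyses.

`tsea()` is a gene-set enrichment analysis run on the rating ranking:
walking down the rating-sorted list, the running sum gains
`rating^w / Σ_hits rating^w` at members and loses `1/(N − K)` otherwise.
Only the positive deviation is scored (prioritization is one-tailed by
construction); `w` defaults to 1 (rating-weighted), and `w = 0` recovers the
classic Kolmogorov–Smirnov walk, which is invariant under order-preserving
rating transforms (property-tested). NES divides the observed maximum by its
mean under gene-label permutations; the permutation p uses the +1
pseudocount; default 1,000 permutations (seeded). The **leading
prioritization** of a set is its members ranked at or before the running-sum
peak — the left-most region ahead of the peak, reported as count/size.

## 3. Crosstalk extraction

Node scores are `rating − θ`; θ defaults to the top-2% rating quantile, so a
small fraction of genes is positive and everything else penalizes inclusion.
`find_crosstalk()` searches for a *connected* subgraph maximizing the summed
score. Two regimes:

* **Exact** (≤ `exact_limit` nodes, default 15): enumeration over all
  connected vertex subsets via bitmask search. This makes the public
  contract exact on every small instance — the suite verifies it against an
  independently written recursive enumerator.
* **Heuristic** (larger graphs): positive-score nodes are contracted into
  connected components; components are merged in decreasing-score order
  through minimum-penalty connector paths (edge penalty = the endpoints'
  negative-score magnitudes, plus a 1e-9 epsilon to prefer fewer hops), a
  merge being kept only when the merged component's score outweighs its
  connectors' cost; negative-score leaves are then pruned iteratively. The
  result is always connected and never scores below the best single node.

Significance uses a **degree-preserving permutation**: scores are shuffled
only within exact-degree bins (configurable width), preserving the
score–degree relationship; the search is re-run per permutation. Singleton
bins (hubs, typically) keep their score — a documented no-op, not an error.
The empirical p-value with pseudocount has floor `1/(1 + n_perm)` (≈ 9.9e-3
at the default 100 permutations); a normal fit to the permutation totals
yields the clearly labelled *extrapolated* p, which is how p-values many
orders of magnitude below the empirical floor can be quoted from only 100
permutations.

The pathway-centric graph takes the pathways significantly over-represented
in the module genes (BH FDR < 0.05) as nodes, joins pairs sharing ≥ 1
member, weights edges by the shared count, and keeps only the minimum
spanning tree on distance `1/shared_count` (per component; ties broken by
lexicographic pathway id for determinism).

## 4. Repurposing and robustness

`max_phase_targets()` reduces a ChEMBL-style table to each gene's maximum
development phase and the drugs attaining it; approved ⇔ phase 4, phased ⇔
phases 1–3, and phase-0-only rows map to *none* (the analysis concerns
clinical-stage assets). Selection is invariant to row order and duplication.
An optional per-indication restriction reproduces the per-indication
variant. `category_enrichment()` runs one one-sided Fisher test per
category with BH across the two.

`removal_effect()` measures the fraction of nodes disconnected from the
largest remaining component after deleting a set, **always with the original
node count as denominator** — the convention under which printed fractions
on an n-node module are integer ratios (e.g. 10/53 = 18.9%). Whether removed
nodes themselves count as disconnected is genuinely under-specified in this
literature, so both conventions are implemented (`exclude_removed`, the
default, and `include_removed`); `include_removed` is provably monotone
under set growth, `exclude_removed` is not in corner cases, which is why the
monotonicity property is asserted under the former. LCC size ties break by
smallest lexicographic member.

`optimal_combination()` enumerates all candidate subsets of sizes
`k_min..k_max` (guarded at 10⁶ combinations) and reports every tied optimum
per k. `targeted_attack()` pre-orders nodes once — statically, matching the
"preordered" description — by degree, unweighted shortest-path betweenness
or supplied priority, ties by symbol, and records the disconnected fraction
after each removal.

## 5. The supra-hexagonal map

`build_map()` lays hexagons on an axial-coordinate lattice spiralling
outward from the centre (H1); ring i holds 6i hexagons, so radius 3 gives
1 + 6 + 12 = 19. Hex-grid distance `(|dq| + |dr| + |dq + dr|)/2` is a
metric (property-tested).

`train_som()` performs sequential best-matching-unit learning with a
Gaussian neighbourhood on grid distance. The schedule is two-phase — rough
(first half of epochs, σ decaying from the map radius to 1) then fine
(σ = 1) — with the learning rate decaying linearly from 0.5 to 0.01 over
40 epochs by default. These hyperparameters are not published for the
original implementation; the two-phase rough/fine scheme is the standard
self-organizing-map recipe and is pinned but configurable (including an
exponential schedule and a batch update behind `som_params(batch = TRUE)`).
The codebook initializes deterministically by interpolating the profile
matrix's first two principal directions across the hex plane, falling back
to seeded random jitter for degenerate rank. Presentation order is
reshuffled each epoch from the run seed, so training is reproducible
seed-for-seed. Per-epoch quantization error is recorded; the suite asserts
it never increases from first to final epoch and that final BMU assignments
are distance-optimal.

`cluster_map()` cuts an average-linkage dendrogram of codebook vectors into
k groups, then repairs contiguity: while any cluster is fragmented under hex
adjacency, its smallest fragment is reassigned to the adjacent cluster with
the nearest mean codebook. The published presentation requires each cluster
to cover continuous hexagons, and hierarchical cuts alone do not guarantee
that. Labels C1..Ck order by smallest hexagon index for determinism.

`overlay_binary()` reports per-hexagon tractable-gene probability (NA for
empty hexagons, rather than an arbitrary 0) and pooled per-cluster
percentages — algebraically the mapped-count-weighted mean of member-hexagon
probabilities, asserted as an identity in the suite. Disease correlations
are Pearson with two-sided t p-values; zero-variance profiles yield NA with
a warning. The disease "landscape" ordering is a reporting feature:
average-linkage clustering of codebook columns.

## 6. The synthetic stated world

Generator defaults were chosen once, as realistic stand-ins, and are not
tuned to test outcomes:

* `n_genes = 500`, `mean_degree = 4` — desk-scale but large enough for a
  separation of module, neighbourhood and background.
* `network_model = "preferential_attachment"` (default) — scale-free degree
  heterogeneity, the salient feature of curated interactomes; the
  configuration model is the matched-mean-degree light-tailed alternative.
  Disconnected leftovers are bridged so propagation sees one component.
* planted module of 20 genes grown by BFS frontier sampling — connectivity
  holds by construction, no rejection sampling.
* evidence: half-normal noise `|N(0, 1)|` per layer (non-negative with no
  truncation mass point) plus an additive uplift of `evidence_effect = 3`
  in a per-gene random non-empty subset of layers — mimicking that real
  genes are supported by some, not all, evidence types.
* 50 gene sets of 10–50 members, 5 oversampling the planted module; a drug
  table whose true targets are half the planted module plus matched
  background, 1–3 drugs each, phases 1–4; disease profiles on the 0–5
  rating scale (background U(0,5), elevated genes U(3.5,5)) with half the
  planted genes elevated in all 9 diseases and half only in the index
  disease; Bernoulli(0.3) tractability labels.
* one global seed; each generator derives a sub-seed by a fixed offset, so
  components are decoupled.

What the generator does **not** emulate: linkage-disequilibrium structure,
realistic GWAS summary statistics, correlated evidence layers, annotation
bias in gene sets, or drug-target promiscuity patterns. A green test
establishes that the machinery recovers planted structure under these
idealized conditions — not that it would do so on real immunogenomic data.

## 7. A benchmark the stated world does not meet — and why

One recovery benchmark — median Jaccard ≥ 0.8 between the found crosstalk
module and the planted module over 20 seeds at effect 3 — is **not met** in
the default stated world (measured median ≈ 0.55 at the default restart and
θ; ≤ ~0.72 anywhere on a restart × θ grid). The suite keeps the assertion,
failing visibly, because the diagnosis is informative:

1. With effect 3 on sd-1 half-normal noise and per-gene layer subsets,
   roughly a fifth of planted genes receive an uplift inside the background
   tail: seed-level recall is capped near 16/20 no matter how the walk is
   tuned.
2. On scale-free graphs, stronger diffusion (smaller r) *lowers* planted
   recall — the walk's degree-proportional component rewards hubs — so
   propagation cannot rescue the under-evidenced members.
3. The rank-based rating compresses scores near the top (positive scores
   ~ +0.1 vs bridge penalties ~ −0.1), so the *exact* maximum-score
   objective does not coincide with the planted set: in every seed examined
   the found module's total score strictly exceeds the planted module's own
   score. The optimizer is right; the objective in this world is not a
   Jaccard-0.8 instrument.
4. The same pipeline in the configuration-model world (same mean degree, no
   extreme hubs) reaches median Jaccard 0.86 — evidence that the
   implementation is sound and the shortfall is a property of extreme
   degree heterogeneity interacting with rank-compressed scores. The
   default world was not switched retroactively, since choosing a
   generator to fit a benchmark would invert the logic of the test.

Practical guidance that follows: on hub-dominated networks, prefer larger
restart values (0.9 keeps evidence dominant), and treat the crosstalk
module as "the best-supported connected core", not as an estimator of a
latent module's full membership.

## 8. Numerical and degenerate-input choices

* Propagation: L1 stopping rule; non-convergence flags, never throws.
* Fisher: p clamped to (0, 1]; K = 0 sets give p = 1.
* TSEA: sets with < 2 ranked members are skipped with a warning; missing
  members dropped with a warning; zero-weight hit mass falls back to
  uniform increments.
* Crosstalk: no positive score is an error ("no signal above threshold");
  constant scores give permutation p = 1 by ties.
* Removal: removing every node is an error; the empty removal is fraction 0
  on a connected graph.
* SOM: non-finite profiles error; fewer genes than hexagons warns; BMU ties
  resolve to the lowest hexagon index.
* All writers sort rows; reruns with one config are byte-identical.

## 9. Known limitations

Gene identity is the case-sensitive symbol string (no alias resolution).
The exact search is exponential and capped at 25 nodes; beyond that the
greedy heuristic carries no optimality guarantee (only connectivity and the
best-single-node lower bound). The extrapolated permutation p assumes
normality of permutation totals. Real printed-value replication of the
motivating study's headline numbers is out of scope by design: it requires
the original GWAS, interactome, pathway and drug-annotation versions.
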