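---
title: "Pruning-based essential protein prediction: models, parameters, and design choices"
author: "lidcNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pruning-based essential protein prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidcNet)
```

## The problem and the model

A protein–protein interaction network (PPIN) is an undirected simple graph
whose nodes are proteins and whose edges are physical interactions.
Essential proteins — those whose deletion is lethal — are enriched in the
densely connected regions of such networks and in protein complexes, but
high-throughput interactomes are noisy: many recorded interactions are
spurious and many peripheral proteins carry no topological signal.
`lidcNet` therefore works in two phases.

**Phase 1** scores the *reliability* of every node and edge. The node
weight of v is the mean degree of its neighbours — a protein embedded
among well-connected partners is likely to be part of real machinery. The
edge weight of u–v is the Jaccard overlap of the two open neighbourhoods:
interactions whose endpoints share many partners are corroborated by the
surrounding topology, while an edge with no common neighbours is
unsupported. Both weight distributions are summarised by their mean
$\alpha$ and standard deviation $\sigma$, and everything below

$$\theta_k = \alpha + k\,\sigma\left(1 - \frac{1}{1+\sigma^2}\right),
\qquad k \in \{1,2,3\}$$

is removed (nodes first, then edges of the node-reduced network, then
degree-0 leftovers). The damping factor $1-1/(1+\sigma^2)$ makes the
cut-off gentle when the weights are homogeneous ($\sigma<1$ gives
$\theta_k \approx \alpha + k\sigma^3$) and approach a plain
$\alpha + k\sigma$ rule when they are dispersed. For edge weights, which
live in $[0,1)$, the three levels are consequently close together; for node
weights they spread further apart.

**Phase 2** runs on the pruned network only. Local interaction density
$\mathrm{LID}(u) = |E(u)|/|V(u)|$ measures how strongly u's neighbourhood
interconnects, where $E(u)$ are the edges among u's neighbours and $V(u)$
are the neighbours with at least one such edge. The complex in-degree
$\mathrm{IDC}(u)$ sums u's interactions with co-members over every complex
containing u. The final score interpolates between them by LID rank:

$$\mathrm{LIDC}(u) = \mathrm{LID}(u)\Bigl(1-\tfrac{\mathrm{RANK}(u)}{N}\Bigr)
 + \mathrm{IDC}(u)\,\tfrac{\mathrm{RANK}(u)}{N}.$$

A protein near the top of the LID ranking is scored essentially by its
local density; a protein far down the ranking can still be rescued by
strong complex membership. LIDC is a convex combination, so it always lies
between LID and IDC. The top 20 % of the LIDC ordering (or fixed top-k
ranges, classically 100–600) is predicted essential.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `level` | — | Cut-off stringency k = 1/2/3 (low/medium/high). Applied to both stages. |
| `context` | `"network"` | Degrees inside the node weight are taken in the full current network. `"induced"` confines them to the closed-neighbourhood subgraph. |
| `sd` | `"population"` | $\sigma$ divides by n. `"sample"` divides by n − 1; at interactome scale the difference is negligible, on toy graphs it is not. |
| `fraction` | 0.2 | Top fraction predicted essential; the count is `ceiling(fraction * N)` (`rounding` switches to `round`/`floor`). |
| `recallDenominator` | `"universe"` | Recall divides by gold-essential proteins present in the evaluated (pruned) network; `"gold"` divides by the full list. |
| `strictGold` | `FALSE` | By default proteins not listed essential count as non-essential; strict mode drops unlisted proteins from fp/tn bookkeeping. |

Where the method description left genuine alternatives open, each switch
above keeps both options testable; the defaults are the package's
choices:

* **Degree context.** The node-weight prose can be read as averaging
  degrees inside an induced neighbourhood subgraph, but the procedure's
  pseudocode applies `deg(u)` over the neighbour set without qualification,
  which is also the standard average-nearest-neighbour-degree quantity
  (igraph's `knn`). The package defaults to the full-network reading and
  keeps `context = "induced"` for sensitivity analysis.
* **Strict inequality.** Removal uses `weight < theta` exactly; values equal
  to the threshold survive. On a k-regular graph $\sigma = 0$ collapses
  $\theta_k$ to $\alpha$ and nothing is pruned — the correct degenerate
  behaviour.
* **Snapshot semantics.** Each stage computes all weights on its input
  network, derives one threshold, and removes everything below it in one
  pass. No recomputation between removals, so results are order-independent.
* **Stranded nodes.** After edge pruning, degree-0 proteins are dropped:
  a protein left without any reliable interaction carries no signal for the
  density-based scores of phase 2 (degree-0/1 proteins are treated as
  non-essential throughout).
* **IDC network.** IDC counts edges of the network being scored — the
  pruned network — not the original one, since phase 2 runs entirely on the
  pruned network.
* **Tie-breaks.** All orderings are descending score, then ascending
  protein identifier. Outputs are byte-deterministic.
* **Zero conventions.** Node weight of an isolated node is 0; LID with no
  edges among neighbours is 0 (the 0/0 case); a protein in no complex has
  IDC 0.

## The synthetic benchmark generator

Real inputs for this method are a DIP-style yeast interactome
(5093 proteins, 24 743 interactions), a complex catalog
(745 complexes, 2167 proteins) and a gold standard (1285 essential
proteins). Those are third-party downloads, so every stage of the package
is exercised instead on a seeded generator that emulates the *structure the
method assumes*: essential proteins sit in dense modules of a sparse
network, and complexes overlap those modules.

`syntheticSpec()` defaults:

| Field | Default | Rationale |
|---|---|---|
| `nBackground` | 600 | sparse bulk; with `pBackground = 0.01` the background mean degree is ~6, typical of interactome periphery |
| `nModules`, `moduleSize` | 8, 10 | module members are a ~12 % minority, as complex members are in curated catalogs |
| `sizeSpread` | 0.3 | module sizes are drawn lognormally around `moduleSize`; curated complex catalogs are strongly right-skewed (CYC2008 spans 2–81 members). Size spread also gives the node-weight distribution the graded right tail that real interactomes have — with exactly equal module sizes the weights are tightly bimodal and the high cut-off degenerates to all-or-nothing. `sizeSpread = 0` restores fixed sizes. |
| `pIn` / `pBackground` | 0.9 / 0.01 | dense planted modules over a sparse background — the recovery conditions the method targets |
| `pAttach` | 0.005 | weak module–periphery attachment |
| `complexCoverage` | 0.8 | the catalog covers most but not all true modules, as real catalogs do |
| `labelNoise` | 0 | fraction of gold labels flipped (uniformly, `floor(noise * n)` flips) to study degradation |

One seed reproduces the whole triple (network, catalog, gold standard)
byte-for-byte through the writers; the three artifacts use stage-derived
seeds (`seed`, `seed + 1`, `seed + 2`) so each can also be regenerated
alone, and the caller's RNG state is restored afterwards. Identifiers are
`P000001…`, sortable and collision-free, which deliberately exercises the
canonical tie-break.

What the generator does **not** emulate: scale-free hub structure,
assay-specific false positives/negatives, overlapping complexes sharing
members, and the 25 % essential base rate of the yeast gold standard
(synthetic base rates are ~12 %). Passing the synthetic recovery tests
therefore shows the pipeline recovers planted dense structure under the
stated noise model — not that the published yeast metrics are reproduced;
that check runs only when the reference files are present.

## Evaluation choices

Precision, recall and F-score are computed over the proteins of the pruned
network (the evaluation universe). The recall denominator is restricted to
gold-essential proteins *in that universe* by default: after aggressive
pruning only a fraction of the 1285-protein list is even scoreable, and
dividing ~190 predictions by 1285 would bound recall near 0.15 regardless
of ranking quality. The top-fraction count uses the ceiling (969 proteins
at 20 % → 194). The jackknife curve is the cumulative count of
gold-essential proteins along the ranking, the standard way to compare
ranking methods over the top-100…600 ranges.

## Problem sizes and numerical checks

The test suite verifies every score and both pruning stages against
independently coded brute-force set-arithmetic oracles on 200 random graphs
of 6–50 nodes (igraph's `knn` serves as a second independent route for the
node weight), checks the closed-form threshold values for the worked sample
{0,1,2,3} to 1e-9, and runs the full pipeline on the default ~680-protein
benchmark: three seeds at all three cut-off levels for the base-rate
comparison, and ten seeds across label-noise 0–0.3 for the degradation
curve. These sizes keep the whole suite under a minute while leaving every
code path exercised at interactome-like density.

## Known limitations

* The method is purely topological; a noisy input network propagates
  directly into the scores, which is why phase 1 exists at all.
* At the high cut-off on small or homogeneous networks the surviving core
  can be very small; `runPipeline()` stops with an informative error if
  pruning empties the network entirely.
* IDC is an unnormalised count, so large complexes dominate it; the rank
  weighting in LIDC mitigates but does not remove this.
* The jackknife machinery compares rankings; it does not test statistical
  significance of differences between methods.
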