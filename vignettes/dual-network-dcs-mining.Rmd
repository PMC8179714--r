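---
title: "Mining dense connected subgraphs in dual networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining dense connected subgraphs in dual networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcsmine)
```

## The model

A *dual network* couples two graphs over one node universe: an unweighted
physical graph $G_p(V, E_p)$ carrying connectivity and a weighted
conceptual graph $G_c(V, E_c)$ carrying relation strength. The object of
interest is a family $X_1, \dots, X_k$ of node sets, each inducing a
connected subgraph of $G_p$, scoring well on

$$\sum_{i=1}^{k} \rho(G_c[X_i]) \;+\; \lambda \sum_{i<j} d(X_i, X_j),$$

where $\rho$ is weighted density and
$d(A,B) = 2 - |A \cap B|^2 / (|A||B|)$ for $A \neq B$ (0 for $A = B$)
rewards mutually distinct subgraphs. $d$ is symmetric, equals 2 exactly on
disjoint sets and always exceeds 1 on distinct sets, so for $k$ pairwise
disjoint subgraphs the distance term contributes exactly $2\binom{k}{2}$.

**Density conventions.** Two forms of weighted density circulate: the
mean-volume form $\sum_{v} vol(v) / |V| = 2W/|V|$ and the edge-sum form
$W/|V|$ familiar from the densest-subgraph literature ($W$ = total edge
weight, $vol(v)$ = summed weight of edges at $v$). They differ only by the
factor 2 — every edge is counted at both endpoints in the first form — and
all algorithmic argmaxes are invariant to the choice. The package defaults
to edge-sum, which is the scale on which its benchmark statistics are
quoted (a 30-node clique with weights near 0.9 has density
$0.9 \cdot 29/2 \approx 13$); `convention = "volume"` switches every
reported density to the doubled scale.

$\lambda$ defaults to 1. It only weights the reported objective; the
mining heuristic never uses it, so the default is inert for the search.

## Step 1: the alignment graph

`build_alignment_graph()` merges the pair into one weighted graph whose
nodes are declared seed pairs $P$ (identity pairs by default). For two
alignment nodes whose physical counterparts are adjacent in $G_p$:

* conceptual adjacency wins: the edge carries the conceptual weight
  (provenance `direct`);
* otherwise, a conceptual hop distance strictly below `delta` adds an edge
  carrying the mean edge weight along one minimum-hop conceptual path
  (provenance `path`).

Design choices a user should know:

* **Hop distance, not weighted distance.** `delta` is an integer hop
  threshold; a weighted shortest path would make it unit-inconsistent.
* **Strict threshold.** The test is `< delta`, so `delta = 1` keeps only
  pairs adjacent in both networks: the alignment graph is then exactly the
  conceptual-weighted intersection of the two edge sets.
* **Deterministic tie-break.** Among tied minimum-hop paths the
  lexicographically smallest node sequence is used, so edge weights never
  depend on traversal order.
* **Role symmetry as a flag.** Physical adjacency is always required and
  `delta` bounds the conceptual distance; `roles = "swapped"` exchanges
  the two networks' roles for experimentation.
* `delta = 4` is the default recorded in the examples, a practical
  setting for sparse relational networks; `delta = 1` is the conservative
  choice when both networks are trusted equally.

Because every alignment edge projects to a physical edge, any connected
subgraph mined from the alignment graph induces a connected subgraph of
the physical network — this is the property that lets step 2 ignore the
dual structure entirely.

## Step 2: peeling, V-Greedy, IWDS

**Greedy peeling** (`greedy_peel()`) deletes a minimum-volume node at a
time, recording every snapshot's density; the best snapshot
(`greedy_densest()`) is the classic 1/2-approximation of the weighted
densest subgraph. Volume ties break by the global lexicographic node
order, making traces fully deterministic and relabel-invariant.

**V-Greedy** (`v_greedy()`) selects by the corrected score
$\rho + 2\rho/|V|$, which slightly favours smaller candidates: two
near-equal-density cliques joined by one light edge score
$2.8$ each versus $2.412$ for their union (unit $K_5$s with a 0.1
bridge), so a single clique is returned where plain peeling returns the
union.

*Connectivity enforcement.* The top-k problem demands connected
subgraphs, but peeling snapshots can be disconnected. Evaluating the
corrected score on the snapshot and then extracting a component is
fragile: with several disjoint near-equal cliques the peel consumes whole
cliques in an order decided by the single globally weakest node, so a
still-unmined clique can disappear from the trace while a remnant of an
already-mined one survives to the end. The package therefore evaluates
the score on **every connected component arising in any snapshot**. This
family is only $|V|$ states large (components only merge as the peel is
replayed backwards, so each re-insertion changes exactly one component)
and is enumerated with a union-find in $O(|E|\,\alpha(|V|))$; the
maximum-score component is returned, ties preferring the earliest
(largest) snapshot. On disjoint planted cliques this makes recovery exact
for every retention fraction tested.

**IWDS** (`iwds()`) produces $k$ subgraphs. $X_1$ is `v_greedy(G)`. At
iteration $i$, with $C_{i-1} = \bigcup_{j<i} X_j$ the covered set:

* Case 1 ($|C_{i-1}| \le f\,|V|$): keep the $\lceil \alpha\,|C_{i-1}|
  \rceil$ covered nodes of highest weighted degree in the *full* graph,
  drop the remaining covered nodes;
* Case 2 ($|C_{i-1}| > f\,|V|$): drop the $\lceil (1-\alpha)\,|C_{i-1}|
  \rceil$ covered nodes of lowest weighted degree.

Uncovered nodes are always retained. As literally stated the two cases
retain the same top-$\alpha$ fraction (they can differ by one node through
rounding); the `f` switch (default 0.5) is kept for fidelity and
forward-compatibility, and this coincidence is deliberate and documented
rather than silently "fixed". $\alpha$ is read as a *fraction* of the
covered set — sweeping $\alpha$ through $0.05 \dots 0.9$ only makes sense
on that reading — with a ceiling so any positive $\alpha$ retains at
least one covered node. Ranking uses weighted degree in the full graph;
ties break by node order.

Each candidate must be a node set distinct from every earlier $X_j$.
Duplicates are resolved by walking the same ranked component family to
the next-best distinct candidate — the states are pairwise distinct sets,
so at most $i$ materialisations are ever needed — and exhaustion (tiny
graphs, `k` too large) truncates the solution with a warning, never a
silent duplicate.

Reproducibility: the miner contains no randomness at all; identical
(graph, parameters) give identical solutions. Generators and the harness
draw everything from a single integer seed.

## The synthetic benchmarks

`make_synthetic1()` plants five disjoint 30-node cliques (edge weights
$\sim U[0.8, 1]$) over a 100-node background (Erdos-Renyi $p = 0.1$ or
$0.2$, or Barabasi-Albert with $m = 10$; weights $\sim U[0, 0.5]$), plus
50 random clique-to-background bridges (weights $\sim U[0, 0.5]$).
`make_synthetic3()` is the overlapping variant: five 30-node cliques, 20
exclusive nodes each, sharing one 5-node block with each cyclic
neighbour (125 planted nodes). `add_noise()` perturbs
$\lceil \ell\,|E| \rceil$ node pairs drawn uniformly from all node pairs:
an intra-clique pair has its edge weight redrawn from $U[0, 0.5]$, any
other pair gains a $U[0.8, 1]$ edge if absent. The pair pool is the full
node-pair universe — the one choice that makes both branches of the rule
reachable; existing non-clique edges hit by the draw are left unchanged
and recorded as such in the provenance table.

What the generator emulates: sharply bounded dense modules over a sparse
weak background, with noise that both erodes modules and adds spurious
strong links. What it does not emulate: heavy-tailed weight
distributions, density gradients within modules, module size variation,
and any coupling between a separate physical topology and the weights
(the benchmark graphs are mined directly, standing in for an alignment
graph). Perfect scores here therefore certify the machinery — recovery of
well-separated planted structure — not performance on real dual networks.

One structural property of the overlapping family deserves emphasis. The
cyclic 5-node overlaps make the *union* of the five cliques strictly
denser than any single clique: about $2125$ internal edges over $125$
nodes give $\rho \approx 15.3$ versus $\approx 13.05$ for one clique, and
no additive correction of the form $2\rho/|V|$ can invert that ordering
($13.05\,(1 + 2/30) \approx 13.92 < 15.3\,(1 + 2/125) \approx 15.54$).
Any peeling-based maximiser of the corrected score must therefore return
the full planted union as its first subgraph, and best-matching F1
against the individual cliques plateaus near $0.45$ — the value the
acceptance script computes — rather than approaching 1. This is a
property of the objective on this geometry, not a failure of the search;
on the disjoint family, where each clique is its own local optimum,
recovery is exact at every $\alpha$, and at noise up to $10\%$ it remains
essentially perfect. At $15\%$ noise the added inter-clique $U[0.8,1]$
edges begin to fuse cliques into unions that outscore single cliques, and
truth-to-detected F1 degrades into the $0.4$–$0.8$ range depending on
$\alpha$ — the same union effect, induced by noise instead of overlap.

## Evaluation

`best_match_f1()` scores a detected family against ground truth in both
directions: F1[t/d] averages, over detected subgraphs, the best
per-pair F1 against any truth set; F1[d/t] averages, over truth sets,
the best F1 against any detected subgraph. The per-pair score is the
standard harmonic-mean F1 $2|A \cap B| / (|A| + |B|)$ (an
arithmetic-mean variant sits behind `average = "arithmetic"` for
sensitivity checks). Matching is free — several detected subgraphs may
share a best-matching truth set — so the two directions expose different
failure modes: missing a truth set depresses only F1[d/t], padding the
solution with redundant subgraphs depresses only F1[t/d].

## Numerical and engineering notes

* Node identifiers are opaque strings ordered by C-locale (radix) sort;
  every tie-break in the package (volume ties, ranking ties, path ties)
  reduces to this one order, so results are locale-independent.
* Degenerate inputs are values, not crashes: an isolated node has volume
  0; a single-node graph peels to one zero-density snapshot; `k` larger
  than the number of obtainable distinct subgraphs truncates with a
  warning; an absent conceptual path is `NULL`, not an error.
* Empty node sets are rejected by the measures (`density`, distance, F1)
  because every formula divides by a set size.
* No floating-point tolerances enter any algorithmic comparison; scores
  are compared directly, with deterministic tie-breaks, so runs are
  bit-reproducible.
* Problem sizes in the shipped tests and acceptance script — 250-node
  instances, 10–30 replicates per cell, exhaustive oracles up to 12
  nodes — were chosen so a full desk-scale validation completes in a few
  minutes while keeping binomial noise on reported means well inside the
  stated tolerances.

## Known limitations

* The per-iteration restriction only ever removes *covered* nodes, so on
  graphs whose densest region is a single overlapping complex the k
  subgraphs can be near-nested variants of it (distinct but similar);
  the distance term in the objective reports, but does not steer, the
  search.
* Real-scale inputs (millions of edges) would want the peel's priority
  queue and the union-find replay in compiled code; the pure-R
  implementation is sized for the benchmark scale.
* Seed-pair generation (sequence similarity, name matching) is out of
  scope: `P` is an input, with identity pairing as the default.
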