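---
title: "Ultrametric networks: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrametric networks: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultranet)
```

## The model

The input is a finite taxon set $V$ and a weighting
$W : \binom{V}{2} \to \mathbb{R}_{>0}$ — observed pairwise dissimilarities,
strictly positive and symmetric, with no other metric assumptions. Two
objects are derived from it.

**The subdominant ultrametric $W^*$.** An ultrametric satisfies the strong
triangle inequality $d(u,v) \le \max(d(u,w), d(w,v))$: every triangle is
isosceles with the two largest sides equal, the geometry of a perfectly
clock-like dendrogram. Among all ultrametrics dominated by $W$ (that is,
$\le W$ pairwise) there is a unique largest one, $W^*$: the supremum of a
bounded family of ultrametrics is again an ultrametric. $W^*$ is also the
closest dominated ultrametric to $W$ in the $L_\infty$ sense, and it has a
purely path-based description: writing $B(P)$ for the **bottleneck** of a
path $P$ (its largest edge weight),
$$W^*(u,v) = \min_{P:\,u \to v} B(P),$$
the minimax or least-resistance value over all paths in the complete graph.

**The ultrametric network $G(V|W)$.** Its edge set is
$E(V|W) = \{\,\{u,v\} : W(u,v) = W^*(u,v)\,\}$ — the pairs whose observed
dissimilarity is already ultrametrically tight. This set coincides with the
union of the edge sets of **all** minimum spanning trees of the weighted
complete graph: every MST edge is tight, and every tight pair lies in some
MST. The network is therefore connected, has between $n-1$ and
$\binom{n}{2}$ edges, and degenerates to the MST exactly when the MST is
unique. Single-linkage clustering heights are the same object seen from the
dendrogram side; the network keeps the tied horizontal structure that the
dendrogram collapses.

## The algorithm

`ultranet()` computes $W^*$ and $E(V|W)$ together in $O(n^2)$. The control
structure is Prim's: a settled set grows one vertex at a time, each pending
vertex $u$ carrying `key[u]`, the lightest edge to the settled set, and
`prec[u]`, the settled endpoint attaining it. When $u$ is annexed through
parent $p$ with key $\kappa$:

- $d(u,p) = \kappa$, and
- $d(u,v) = \max(\kappa,\, d(p,v))$ for every other settled $v$.

The rule is sound because $\kappa$ is the cheapest crossing of the cut
separating $u$ from the settled set: any $u$–$v$ path must cross the cut at
cost $\ge \kappa$, and the path through $p$ achieves
$\max(\kappa, d(p,v))$. Settled-pair values are never revisited — at every
step $d$ restricted to the settled set *is* the subdominant ultrametric of
the restricted input — which is where the factor-$n$ saving over the
$O(n^3)$ pivot closure comes from. After the last annexation the edge set is
read off by the membership test $W(u,v) = d(u,v)$.

Numerical choices:

- **Membership tolerance.** Every $d$-value is a maximum of input weights,
  so a mathematically tight pair is bit-equal in floating point and integer
  inputs compare exactly. The test still allows a $10^{-12}$ relative slack
  as insurance for inputs that were themselves computed in floating point.
- **Seed and ties.** The seed vertex is the first label; the result is
  seed-independent (tested by refitting under all rotations of the label
  order). Equal keys are broken by byte-wise label order; $W^*$ and the
  edge set are tie-invariant, so this affects nothing observable — it only
  pins down internal iteration order. All label sorting in the package is
  byte-wise (radix), so outputs do not depend on the session locale.
- **Queue.** The pending set is scanned linearly each iteration rather than
  kept in a Fibonacci heap: on a complete graph both give $O(n^2)$ overall,
  and the scan has smaller constants and no allocation.
- **Instrumentation.** `$steps` counts elementary operations
  (initialization, queue scans, $d$-updates, key updates). It is a
  deterministic function of $n$ alone, about $2n^2$; the test suite fits a
  log-log slope over $n = 50\ldots400$ and requires it in $[1.8, 2.2]$.

Correctness is anchored to three independent brute-force references shipped
in the package (size-capped, so users can re-run the cross-validation):
`bottleneck_closure()` (the $O(n^3)$ pivot closure), `all_mst_edge_union()`
(Prüfer-sequence enumeration of all $n^{n-2}$ spanning trees), and
`min_bottleneck_by_paths()` (exhaustive simple-path search). The update rule
above is this package's reconstruction of the incremental computation from
the algorithm's loop invariants; the closure oracle, not the
reconstruction, is the authority the tests enforce — the suite checks
entrywise agreement on hundreds of random instances, exactly for integer
weights and to $10^{-12}$ relative for continuous ones.

## Tunable parameters

- **`delta`** (dissimilarity units, default 0): relaxed membership
  $W(u,v) \le W^*(u,v) + \Delta$. The tolerance is *additive* — the
  defining formula is additive, so a relative version would be a different
  model. $\Delta = 0$ is the exact network; the edge set grows monotonically
  and reaches the complete graph at $\Delta = \max W$. The boundary is
  inclusive: a pair whose deviation $W - W^*$ equals $\Delta$ exactly is
  admitted. On the four-point worked example (`canonical4()`, deviations
  $ac = ad = 2$, $bd = 3$) this means $\Delta = 2$ admits *both*
  deviation-2 pairs at once.
- **`augment_threshold`** (dissimilarity units, default `NULL` = off):
  triangles whose perimeter strictly exceeds the threshold are replaced by
  a median star. 0 processes every triangle; larger values leave small,
  biologically plausible triangles alone and only resolve heavy ones. The
  two parameters are deliberately separate flags: one relaxes membership,
  the other controls Steiner-vertex insertion, and they compose in that
  order (exact network → relaxation → augmentation).

## Artificial median vertices

For a triangle on $u, w, y$ the median (Steiner point) distances are the
Gromov products
$$d(x,u) = \tfrac{1}{2}(d_{uw} + d_{uy} - d_{wy})$$
and cyclic permutations — the unique solution of the three path equations
$d(x,u) + d(x,w) = d_{uw}$, etc. The replacement star preserves all three
pairwise distances exactly and weighs half the perimeter, so total edge
weight never increases and strictly decreases whenever a triangle is
processed. The formula is the standard three-point tree-metric
construction; it is the only assignment that realizes the distances, which
is the property the operation exists to preserve.

Processing order is canonical — perimeter descending, ties by sorted label
triple — so the outcome is independent of edge input order (verified by
shuffling on random instances). When two candidate triangles share an edge
the heavier one wins and the other is skipped as `edge-consumed`.
Degenerate triangles (triangle inequality tight or violated, as can happen
on $\Delta$-relaxed networks whose weights are raw dissimilarities) would
produce a zero- or negative-length star edge; they are skipped with a
warning rather than merging taxa, because input taxon identity must
survive the operation. Augmentation is a single pass: artificial vertices
do not seed new candidate triangles, which also rules out cascades.
Artificial vertices are named `N1, N2, ...` in creation order and carry a
boolean `artificial` attribute plus a provenance record of the triangle
they replaced.

## The STR front end

Y-chromosome STR haplotypes are vectors of integer repeat counts, one per
locus. The dissimilarity is the weighted stepwise (L1) distance
$$W(i,j) = \sum_l w_l\,|c_{il} - c_{jl}|,$$
each unit of repeat difference counting as one mutational step under the
single-step mutation model. *The formula is this package's reconstruction*:
it is the standard choice for Y-STR data, flagged as such in the function
documentation. Identical haplotypes are merged into a single vertex (label
`id1+id2`) rather than carried at distance zero, because the model requires
$W > 0$.

Weights come from mutation rates via `str_weights()`: loci are binned into
terciles by rate rank and assigned weights from $\{4, 2, 1\}$. Two
orientations are exposed because "weight reflecting the mutation rate" is
genuinely ambiguous: the default `slow-heavy` gives stable loci weight 4
(a difference at a slow locus is stronger evidence of divergence — the
standard down-weighting of volatile markers), while `fast-heavy` assigns
weight proportional to the rate rank. Tied rates share a bin (equal rates
can never receive unequal weights), so a panel of identical rates
collapses into the first bin — all weight 4 under the default.

## The synthetic survey generator

`str_fixture(n_individuals, n_loci, n_populations, seed)` emulates a
multi-population haplotype survey: per-population locus centroids drawn
uniformly on 8–24 repeats (between-population per-locus differences of
several steps), individuals scattered around their centroid by
single-repeat jitter ($\pm 1$ with probability 0.15 each side), populations
assigned round-robin, and per-locus mutation rates drawn log-uniformly on
$[5\times10^{-4}, 10^{-2}]$ per generation — a realistic Y-STR range.
Sampled haplotypes are kept distinct by re-drawing jitter on collision,
matching the survey design in which each network vertex is a distinct
haplotype. The default test shapes are 54 individuals × 12 loci over 10
populations and 41 × 7 over 11.

What the generator does *not* emulate: homoplasy across deep lineages
(independent mutations converging on the same repeat count), locus-specific
range constraints, multi-copy and null alleles, and any real migration
geometry. Passing tests therefore demonstrate that the pipeline recovers
planted block structure and produces connected, population-clustered
networks of the right shape — not that it reproduces any particular real
human phylogeography.

## Problem sizes used in the test suite

Oracle equivalence runs on 200 random instances with $n \in [3, 40]$;
MST-union equivalence on 100 tie-heavy instances with $n \le 7$ (at
$n = 7$ the enumerator decodes $7^5 = 16\,807$ Prüfer sequences in bulk);
path enumeration is cross-checked for $n \le 8$; the step-counter fit uses
$n = 50, 100, 200, 400$. These sizes make the full suite run in well under
a minute while exercising every tie-handling and tolerance path; all random
instances are seeded and reproducible.

## Known limitations

- The exhaustive references grow as $n^{n-2}$ and are hard-capped
  ($n \le 9$ for tree enumeration, $n \le 8$ for path enumeration).
- Augmentation only resolves 3-cycles; it does not search for optimal
  Steiner trees or optimal realizations in the tight span, and it does not
  iterate to a fixed point.
- Subdominant $\Delta$-ultrametrics (re-closing the relaxed object) are a
  different construction and are not implemented.
- The algorithm is static: inserting or deleting a taxon means refitting.
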