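# ultranet

Subdominant ultrametrics and ultrametric phylogenetic networks from
dissimilarity data.

## The problem

Distance-based phylogenetics usually reduces a dissimilarity matrix to a
single minimum spanning tree, discarding every equally good alternative
connection. When the data are reticulate or noisy — Y-chromosome STR
(microsatellite) haplotypes across human populations are the motivating
example — the tied and near-tied connections carry real signal about
kinship and migration, and a *network* is the more honest summary.

Given a set of taxa `V` and a symmetric, strictly positive dissimilarity
`W` on pairs of taxa, this package computes:

- **The subdominant ultrametric `W*`** — the unique largest ultrametric
  (metric with the strong triangle inequality
  `d(u,v) <= max(d(u,w), d(w,v))`) dominated by `W`. Equivalently, `W*(u,v)`
  is the *minimax path value*: the minimum over all paths from `u` to `v` of
  the largest edge weight (bottleneck) along the path.
- **The ultrametric network `G(V|W)`** — the graph whose edges are exactly
  the pairs with `W(u,v) = W*(u,v)`. This edge set equals the union of the
  edge sets of *all* minimum spanning trees of the weighted complete graph,
  so the network is the MST made robust to ties.

Both are produced simultaneously by a Prim-style incremental algorithm in
optimal `O(n^2)` time, a factor `n` faster than the Floyd–Warshall-style
`O(n^3)` closure (which ships as a brute-force cross-check, together with an
exhaustive spanning-tree enumerator and a simple-path enumerator).

Two relaxations are supported:

- **Δ-relaxation**: admit every pair with `W(u,v) <= W*(u,v) + Δ`, growing
  connectivity monotonically with Δ (an `O(n^2)` postprocess).
- **Artificial median vertices**: replace a triangle whose perimeter exceeds
  a threshold by a three-edge star through a new (Steiner/median) vertex
  that realizes the three pairwise distances exactly at half the weight,
  modeling an unobserved ancestral haplotype.

An STR front end turns haplotype tables (individuals × locus repeat counts)
into weighted stepwise (L1) distances, with per-locus weights in {1, 2, 4}
derived from mutation rates.

## Worked example

```r
library(ultranet)

W <- canonical4()   # 4 taxa: ab=1 bc=2 cd=3 ac=4 ad=5 bd=6
fit <- ultranet(W)
fit
#> Ultrametric network (4 vertices)
#>   exact edges: 3
#>   elementary steps: 15

fit$edges
#>   u v weight wstar exact
#> 1 a b      1     1  TRUE
#> 2 b c      2     2  TRUE
#> 3 c d      3     3  TRUE

as.matrix(fit)      # the subdominant ultrametric W*
#>   a b c d
#> a 0 1 2 3
#> b 1 0 2 3
#> c 2 2 0 3
#> d 3 3 3 0
```

The network is the path `a–b–c–d`: the unique MST. `W*(a,d) = 3` because the
best route from `a` to `d` never crosses an edge heavier than 3
(`bottleneck(fit, "a", "d")` returns it directly). Relaxing by Δ = 2 admits
the two pairs whose dissimilarity exceeds their ultrametric value by exactly
2:

```r
delta_network(fit, 2)$edges
#>   u v weight wstar exact
#> 1 a b      1     1  TRUE
#> 2 a c      4     2 FALSE
#> 3 a d      5     3 FALSE
#> 4 b c      2     2  TRUE
#> 5 c d      3     3  TRUE
```

An STR pipeline, end to end:

```r
tab <- str_fixture(54, 12, 10, seed = 1)   # synthetic 10-population survey
fit <- ultranet(str_dissimilarity(tab), delta = 0)
write_network(fit, "survey.graphml")       # weights + W* as edge attributes
plot(fit)
```

The same pipeline is scriptable from a shell via the installed
`exec/ultranet` launcher (`compute`, `from-str`, `oracle`, `fixture`
subcommands; `--delta`, `--augment-threshold`, `--format`, `--seed`, ...).

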