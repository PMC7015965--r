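---
title: "Tree maps of high-dimensional data: models, parameters and numerical choices"
author: "mstmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree maps of high-dimensional data: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstmap)
```

## The model

`mstmap` draws a large collection of high-dimensional records — binary
feature sets such as folded molecular fingerprints or word-occurrence
sets, or non-negative weighted vectors such as expression profiles — as a
tree on the plane.  The pipeline has four phases:

1. **Sketching and indexing.**  Each record is reduced to a `d`-component
   MinHash signature whose per-component collision probability equals the
   Jaccard similarity of the underlying sets (for weighted vectors, a
   consistent-weighted-sampling sketch with the same property for the
   generalized Jaccard index `sum(min)/sum(max)`).  Signatures are indexed
   in an LSH forest of `l` prefix trees, each keyed on `d / l` consecutive
   signature components.
2. **Approximate k-NN graph.**  Every record queries the forest for its
   `k` approximate nearest neighbors with an augmented query: candidate
   records are gathered across all trees in order of decreasing shared
   key-prefix length until at least `k * kc` distinct candidates are in
   the pool (the crossing prefix level is always consumed in full), then
   the pool is re-ranked by the signature-level estimated Jaccard
   distance.  Edges carry that estimated distance as their weight.
3. **Minimum spanning forest.**  Kruskal's algorithm with union-find
   reduces the neighbor graph to a forest: per connected component, a
   spanning tree of minimum total weight.  Removing all cycles — rather
   than pruning, as neighbor-embedding methods do — is what makes the
   final drawing a tree and keeps the layout problem light.  Outliers at
   Jaccard distance 1 from everything stay as singleton components.
4. **Layout.**  Each tree is drawn by a multilevel spring-electrical
   model: adjacent vertices attract with magnitude $d^2/K$, all pairs
   repel with magnitude $pK^2/d$ ($K = 1$ is the unit spring length), and
   the forest is coarsened by maximal edge matchings, laid out at the
   coarsest level from seeded random positions, then prolonged and
   refined level by level.  Repulsion is approximated by a Barnes–Hut
   quadtree.  Components are packed on a grid, largest first, with
   margins equal to each component's bounding-box diagonal.

The estimator, index, graph algorithms and layout are deterministic
functions of the input and one master seed; reruns reproduce output files
byte for byte.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d` | 128 | signature length; estimator SE for a pair at similarity $J$ is $\sqrt{J(1-J)/d}$ |
| `l` | 8 | prefix trees; more trees raise candidate diversity and memory |
| `k` | 10 | neighbors per record in the graph phase |
| `kc` | 10 | pool augmentation; the query gathers ≥ `k*kc` candidates |
| `p` | 1/65 | repulsion-to-spring ratio; the one knob to grow with data size (larger `p` spreads the drawing) |
| `theta` | 0.9 | quadtree opening angle; 0 switches to exact pairwise forces |
| `iterations` | 100 | force iterations at the coarsest level, halved per finer level with floor 30 |

`d` dominates fidelity: every downstream quantity (edge weights, neighbor
ranking) sees the original space only through the signatures.  `k` and
`kc` matter less for the drawing than for how faithfully the graph phase
recovers exact nearest neighbors.

## Numerical choices

- **Hashing.**  Item indices are scrambled by a seeded 4-byte simple
  tabulation hash before the `d` affine maps `(a*y + b) mod (2^31 - 1)`
  are applied.  Affine families alone are 2-universal but not min-wise
  independent enough: on structured inputs (runs of consecutive indices)
  their minima correlate and the Jaccard estimate is visibly biased;
  tabulation hashing removes the structure.  All modular arithmetic is
  carried out exactly in doubles (every intermediate stays below
  $2^{53}$).
- **Weighted sketches.**  The consistent-weighted-sampling component is
  the pair (argmin dimension, discretized log-weight level), packed into
  a single exactly-representable double `k * 2^32 + t + 2^31` so the
  plain and weighted flavors share one comparison and indexing code
  path.  This is one published variant among several with the required
  collision property; it is isolated behind the signature `flavor` so an
  alternative could be swapped in.
- **Prefix trees** are sorted key arrays with binary search and
  precomputed longest-common-prefix values of adjacent keys, not pointer
  tries: the set of entries sharing a given prefix with a query is a
  contiguous run around its insertion position, so descending-depth
  candidate gathering is an outward expansion with a running minimum —
  cache-friendly and exactly reproducible.
- **Tie-breaks.**  Everywhere by ascending record id (query ranking,
  Kruskal's edge order `(w, u, v)`, component numbering, matching order).
  A total order at every step is what makes reruns bit-identical.
- **Layout integration.**  Displacement per iteration is the force capped
  at the current step length (`F * min(1, step/|F|)`), with the step
  multiplied by 0.9 each iteration.  The capped rule is smooth in the
  force near equilibrium, which keeps the descent inside one basin;
  refinement levels start at step 0.25 (the prolonged state is already
  near equilibrium), the coarsest level at step 1 from seeded random
  positions with exact pairwise forces.  Each level returns its
  minimum-energy iterate (energy = sum of squared force magnitudes), so
  refinement can never end above its starting energy.
- **Quadtree.**  The opening test is `(side + offset)/dist < theta`,
  where `offset` is the distance from the cell center to its center of
  mass, and a cell containing the query point is always opened (this
  avoids approximating a point's own cell, the main error source at
  aggressive `theta`).  Multipole expansion is deliberately not
  implemented; the quadtree has the same asymptotic contract and far
  less machinery.
- **Degenerate inputs.**  Empty sets and all-zero vectors are refused at
  encoding time (fail fast, before they poison an index); the one
  documented exception is mean-binarization of a constant vector, which
  legitimately yields an empty set and is left to the caller.  Two empty
  sets have Jaccard similarity 1 by convention.  Coincident points in
  the layout are separated deterministically along a fixed axis.

## The synthetic generator

`generate_clustered_sets()` emulates clustered sparse binary data:
each cluster owns a random core of `core_size` features, cores are
mutually disjoint, records drop each core item with probability `p_drop`
and gain `Poisson(p_add)` uniform noise features.  Disjoint cores make
the noiseless ground truth analytic (within-cluster Jaccard exactly 1,
cross-cluster exactly 0), and under independent drops the expected
within-cluster similarity has the closed form
$(1-p_\mathrm{drop})^2 / (1 - p_\mathrm{drop}^2)$, which the test suite
checks empirically.  The defaults (universe 4096, core 128,
`p_drop = 0.1`, `p_add = 10`) give within-cluster similarity near 0.7 —
sparse sets of roughly 120 items, a plausible stand-in for hashed
fingerprint-like data.

What the generator does **not** emulate: real fingerprint bit-frequency
skew, correlated substructures, or a continuum of similarities.  Within a
cluster, records are exchangeable, so pairwise distances concentrate
tightly around one value.  One consequence is worth understanding: when
the gap between a record's 10th and 30th exact nearest neighbors is
smaller than the signature estimator's sampling error at the chosen `d`,
*no* index that ranks by signatures can recover the exact top-10 reliably
— recall against an exact-Jaccard oracle saturates well below 1 even with
a perfect candidate pool.  Passing locality and structure tests on this
generator therefore demonstrates the pipeline's contracts, not that
recall on real data (which has a continuum of similarities) would be
equally limited, nor that it would be as high.

`generate_weighted_vectors()` plays the same role for the weighted
flavor: disjoint-support non-negative prototypes (orthogonal, so the
noiseless cross-cluster generalized Jaccard is 0) plus zero-truncated
Gaussian noise.

## Problem sizes used by the checks

The test suite and the acceptance script exercise: estimator fidelity on
100 seeded random pairs at `d = 512`; index recall on 2000 records in 5
clusters (`d = 512`, `l = 8`, `k = 10`, `kc ∈ {1, 2, 5, 10}`) against a
brute-force exact-Jaccard oracle; Kruskal against exhaustive
spanning-tree enumeration on 200 random connected graphs of at most 8
vertices; the full pipeline with locality diagnostics on 500 records over
10 seeds; and layout sanity on 100 random trees of up to 500 vertices.
These sizes were chosen so each check has enough replication for its
stated tolerance while the whole suite stays comfortably interactive.

## Known limitations

- Phase I/II quality is bounded by the signature resolution `1/d`; the
  index never consults exact distances (the brute-force path exists only
  as a test oracle).
- No dynamic deletion from the forest, no multi-probe queries, and no
  alternative metrics inside the index; other metrics enter through the
  edge-list bypass.
- The layout optimizes a non-convex energy: different seeds give
  different, equally valid drawings.  Determinism holds for a fixed seed
  and platform floating-point behavior, not across compilers that reorder
  arithmetic.
- Topological evaluation distances are hop counts, which tie heavily on
  trees; ranks under that metric are conservative for points with many
  equally-near tree neighbors.
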