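---
title: "Methods: comparing planar biological distribution networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing planar biological distribution networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planarnet)
```

## The model

A distribution network is represented as a simple undirected graph whose
nodes carry 2D coordinates. Edges are physical conduits — mycelial cords,
surface vessels — assumed straight (tortuosity is neglected), and unweighted:
no radius or conductance information enters the analysis, so every metric
describes the *structural backbone* only. Coordinates are unitless; derived
lengths inherit whatever unit the input uses, and all cross-network
comparisons rely on relative or normalised quantities, so the unit never
matters.

Node type labels distinguish ordinary junctions (`branch`), tips
(`endpoint`), a mycelium's food source (`inoculum`), and degree-1
vasculature nodes where a vessel dives into the tissue
(`penetrating_arteriole`). The `reduce_stubs()` transformation removes the
latter together with their single incident edge — once, not recursively —
producing the "reduced" backbone representation.

Connectivity is enforced at load time because every pathway-based metric
assumes it; an `allow_disconnected` override exists for damaged or derived
networks. Duplicate coordinates are a warning (they only matter for the
geometric constructions, which reject them); zero-length edges are an
error.

## Metrics

*Topological*: mean degree $\langle k\rangle = 2M/N$; average local
clustering $C$ (degree-1 nodes contribute zero); the alpha index
$\alpha = (M-N+1)/(2N-5)$, the fraction of independent cycles realised out
of the planar maximum; topological efficiency
$E^t = \frac{1}{N(N-1)}\sum_{i\neq j} 1/l^t_{ij}$ with hop-count shortest
paths and unreachable pairs contributing zero; and edge betweenness with
unordered pairs counted once and ties split fractionally.

*Spatial*: wiring length $W = \sum_{i>j} A_{ij} D_{ij}$; physical
efficiency computed from shortest paths in summed Euclidean edge length,
normalised by the complete graph on the same node positions (the natural
reading of a "fully connected network with the same number of nodes" —
same *positions*, straight-line links); physical edge betweenness; and the
Spearman correlation $\rho$ between the two betweenness maps. Flow is
assumed bidirectional: all shortest paths are undirected.

The unordered-pair betweenness convention is recorded because only the
*rank* correlation between the topological and physical maps is consumed
downstream, which is invariant to it.

## Null models

Three reference constructions share the empirical network's node positions:

- **Euclidean MST** (Prim's algorithm on pairwise distances): the
  minimal-wiring connected planar graph; lower anchor.
- **Greedy triangulation** (GT): node pairs connected in ascending distance
  whenever the straight segment crosses no accepted edge. Ties break
  deterministically by (distance, smaller id, larger id); crossing means a
  proper interior intersection or collinear overlap, while shared endpoints
  are allowed. In general position the result has $3N - 3 - h$ edges ($h$
  convex-hull points). This is the expensive, redundant upper anchor.
- **Connected degree-preserving rewiring**: double-edge swaps that reject
  self-loops, duplicates, and disconnections. "About 15 swaps per edge" is
  counted in *accepted* swaps, with attempts capped at $100M$; both counts
  are reported per ensemble member. Members that admit no valid swap (a
  star) are returned unchanged and flagged.

Ensemble normalisation $X/\langle X_\mathrm{rewire}\rangle$ reports a
missing value with a diagnostic when the ensemble mean is zero — a real
occurrence for clustering, since triangles are rare in sparse rewired
graphs.

## Rentian scaling

Topological scaling is estimated by recursive balanced bisection: a
spectral (Fiedler-vector) split of each partition's induced subgraph,
followed by greedy single-move refinement under a 10% balance tolerance,
recursing while a partition has at least `min_partition = 8` nodes.
Each bisection contributes two samples $(n, m)$ — the node count of each
half and the *cut* created by that bisection. Counting instead all
full-network edges leaving each partition systematically flattens the
scaling on finite networks (on an $L\times L$ mesh the tiling average is
$m = 4\sqrt{n}(1-\sqrt{n}/L)$, whose log–log slope collapses at large $n$);
the cut definition recovers the theoretical mesh exponent $1/2$ on lattice
fixtures, which is the calibration standard we hold the partitioner to.
Five randomized runs (refinement tie-breaks differ) are averaged; the
exponent is the mean of per-run OLS slopes of $\log_{10} m$ on
$\log_{10} n$, with $n = 0$ or $m = 0$ samples excluded.

Physical scaling uses 5000 axis-aligned square partitions with centres
uniform and sides uniform in $[s_\min, s_\max]$: $s_\min$ is the side whose
expected node content is 2 given the global density over the convex hull;
$s_\max$ is found by bisection as the largest side for which at least 1% of
candidate boxes fit inside the hull (all four corners inside — which, by
convexity, contains the whole square). Half-open boxes avoid double
counting; $m$ counts edges with exactly one endpoint inside (an edge whose
segment merely passes through the box is not a boundary crossing in the
node-partition sense of Rent's rule).

The theoretical minimum $p_\min = \max(1 - 1/d_E,\ t)$ with $d_E = 2$; the
summary also reports $t/\langle t_\mathrm{rewire}\rangle$,
$p/\langle p_\mathrm{rewire}\rangle$ (rewired members keep the source
coordinates, and identical box seeds make the physical comparison exact),
$p_\min/p$, and
$\delta = p_\min/p - \langle p^\mathrm{min}_\mathrm{rewire}/p_\mathrm{rewire}\rangle$,
positive for embeddings more wiring-efficient than their rewired
counterparts.

## Robustness

$R$ is the percentage of edges removed, in a uniformly random order, at
which the largest connected component first drops below $N/2$ (strict
inequality; the choice only matters at parity and is documented rather than
configurable per call). Removal sequences are evaluated exactly by reverse
union-find, and $R$ is averaged over 20 independent sequences.

The efficiency-decline experiment removes an independent random subset of
$\lfloor fM \rfloor$ edges for each $f$ on the grid $0, 0.004, \ldots, 0.6$
(20 trials per $f$, independent across fractions — not nested along one
permutation) and tracks $\langle E^p(f)/E^p(0)\rangle$, with unreachable
pairs contributing zero efficiency. The initial damage response is the OLS
slope over $f \in [0, 0.1]$.

## Relative measures and statistics

$W_\mathrm{rel}$, $E^p_\mathrm{rel}$, $R_\mathrm{rel}$ rescale each
quantity between its MST (0) and GT (1) values on identical node positions.
The wiring and efficiency anchors are exact identities; the robustness
anchors hold to Monte-Carlo precision. Empirical values can fall outside
$[0,1]$ (a sparse network can be less efficient than its MST); they are
reported, not clipped.

Two-group comparisons use the two-sided pooled-variance Student t-test by
default, with Welch available. The pooled default is not arbitrary: on the
built-in node/edge counts of the 22 reference reconstructions, the pooled
test reproduces the published significance levels of the count-derived
metrics to their printed precision, while Welch's test does not. SEM is
$s/\sqrt{n}$. No multiple-testing correction is applied across the report
rows, matching standard practice for this kind of descriptive comparison.

## Synthetic generators

The generators produce study-shaped inputs so that every downstream stage
is testable without the original reconstructions. Both regimes target an
exact cycle count $c = \mathrm{round}(\alpha^\ast (2N-5))$, so the achieved
alpha is within half a cycle, $0.5/(2N-5)$, of the target.

- **Mycelium-like**: points sampled with a radially decaying density around
  a central inoculum (radius $\propto u^{0.7}$, $u$ uniform — a modelling
  convenience, as no empirical density profile is documented); the greedy
  triangulation supplies a maximal planar scaffold standing in for the
  densely anastomosed mat; edges are then thinned uniformly at random among
  non-bridges until $c$ cycles remain. Uniform thinning leaves loops at all
  length scales and keeps mean degree in $[2, 3]$ for
  $\alpha^\ast \le 0.25$.
- **Vasculature-like**: uniformly scattered junction points; the backbone
  is the Euclidean MST *plus* $c$ loop edges drawn uniformly from the
  remaining greedy-triangulation edges — a minimal-cost vessel tree with
  sparse anastomotic redundancy, which is what gives the regime its
  low-cost-yet-efficient character. A prescribed fraction of additional
  degree-1 `penetrating_arteriole` nodes is then attached by short
  non-crossing edges to random backbone nodes; stub edges change neither
  the cycle count nor, therefore, the alpha index.

An earlier candidate mechanism — thinning the triangulation longest-edge
first — was rejected at design time because it yields networks *less*
physically efficient than their own MST, unlike either biological system.

What the generators do **not** emulate: real growth dynamics, tortuous
edges, the radius hierarchy, the inoculum "super-node" edge concentration,
and any coupling between stub placement and backbone loop structure.
Consequently, passing the synthetic-cohort tests demonstrates that the
*pipeline* recovers the regime contrasts it is fed (loop density, stub
fraction, wiring investment), not that the generator reproduces every
coordinate-dependent published value. One known departure: penetrating
arteriole stubs soften the early efficiency decline, so across the *mixed*
two-regime cohort the decline slope correlates only weakly with relative
wiring; the slope–wiring correlation is therefore assessed across a
loop-density sweep of the mycelium mechanism, where the density–robustness
logic applies cleanly.

## Numerical choices

- Geometric predicates (crossing tests) use double-precision orientation
  signs; fixtures live on integer lattices where these are exact, and
  random coordinates avoid degeneracy almost surely. Collinear overlap and
  T-junctions count as crossings.
- Shortest-path ties are split fractionally; on unit-length fixtures the
  physical and topological betweenness maps coincide exactly.
- All stochastic operations take a single integer seed; per-trial,
  per-member, and per-run sub-seeds are derived from it, and identical
  configurations reproduce byte-identical outputs. Compiled kernels use a
  fixed 64-bit generator fed by those sub-seeds.
- Written coordinates carry 10 significant digits; CSV round trips
  reproduce edge sets and labels exactly.

## Problem sizes

The test-suite cohorts use the node counts of the 22 reference
reconstructions (543–2650 nodes) for the two-group contrast, a 24-network
loop-density sweep at $N = 150$ for the decline-slope correlation, 16×16
and 32×32 lattices for Rent calibration, and 6-point exhaustive
enumerations (all $6^4$ labelled spanning trees) for the MST oracle —
sizes chosen so each property is measured where its signal is clear and the
whole suite runs in minutes on one CPU.

## Limitations

Unweighted edges ignore conductance, which is known to dominate transport
in real vessels and cords; straight-edge wiring underestimates tortuous
cost; the Rent partitioner is a heuristic (exact min-cut is intractable),
so exponents are calibrated, not guaranteed; and the generators are
structural emulators, not growth models — conclusions about real systems
require real reconstructions, for which the package's loaders, metrics and
pipeline apply unchanged.
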