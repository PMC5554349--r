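---
title: "Models and algorithms behind netvis3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and algorithms behind netvis3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netvis3d)
```

netvis3d is a headless 3D visualization engine for biomolecular networks:
protein–protein interaction maps, gene/disease/drug multi-layer networks,
metabolite correlation networks, residue-contact graphs.  Everything runs
from scripts — layouts, clustering, edge bundling, topology statistics, and
rendering to PNG snapshots and rotating GIF movies — with no display,
windowing system, or GPU.  This vignette explains the models, the tunable
parameters, the numerical choices, and what the test suite does and does
not establish.

## The graph model

A network is a node table and an edge table (`nv_graph`).  Topologically the
graph is always treated as undirected: the `directed` edge flag is a display
attribute that draws arrowheads, never an input to layout, clustering, or
statistics.  Duplicate edges between the same unordered pair are collapsed
with their weights summed, so repeated experimental evidence for an
interaction accumulates rather than being silently dropped.  Self-loops are
rejected with a warning, because no algorithm in the package consumes them.
Edge weights are positive reals and are interpreted as *lengths* by every
shortest-path computation; inputs where weight means affinity (bigger =
closer) can be inverted with the `weights = "similarity"` option of
`edge_betweenness`.

## Force-directed layouts

The core energy model is the classical spring–charge system: nodes repel
with force $k^2/d$, adjacent nodes attract with $d^2/k$, where
$k = (\mathrm{volume}/n)^{1/3}$ is the natural edge length in a layout cube
of the given volume (default $10^3$ cubic layout units).  The two forces
balance exactly at $d = k$, so an isolated edge settles at separation $k$ —
a property the test suite checks against the closed form.

Choices the force model leaves open:

* **Iteration budget.** Size-adaptive: $\min(1000, \max(50,
  30\lceil 10^4/n\rceil))$, a non-increasing function of $n$, so small
  graphs converge tightly and a 5,000-node network stays interactive.
* **Cooling.** Temperature (the per-step displacement cap) decays linearly
  from $k$ to zero by default; a multiplicative factor is available.
* **Coincident nodes.** The printed forces diverge at $d = 0$, so exactly
  coincident nodes are jittered by $10^{-4} k$ using the run's seeded
  generator before iteration.
* **Bounding.** Positions evolve unclamped and the final configuration is
  rescaled *uniformly* about its centroid to fit the cube.  Per-iteration
  wall clamping was tried and rejected: it pins repulsion-dominated
  configurations to the walls, saturating cluster separation and masking
  the effect of edge cutting.  Uniform rescaling preserves every distance
  ratio while honoring the bounded-volume contract.

All layouts are deterministic given a seed; the RNG state of the session is
saved and restored around every seeded computation.

## Lin-log (r-PolyLog) layouts

The r-PolyLog energy
$$U_r(p) = \sum_{\{u,v\}\in E} \tfrac1r \lVert p(u)-p(v)\rVert^r
 - \sum_{\{u,v\}\subset V} w_u w_v \ln \lVert p(u)-p(v)\rVert$$
interpolates between cluster-separating and uniform layouts: $r=1$ is the
LinLog model whose minima group nodes by cut density, and at $r=3$ the
single-edge equilibrium coincides with the spring–charge model at $k=1$.
Node-repulsion mode has $w_u = 1$; edge-repulsion mode weights each pair's
repulsion by $\deg(u)\deg(v)$, which stops hubs from crowding the center.
The pair sum runs over unordered distinct pairs only — the diagonal term is
undefined and excluded.  Optimization is plain gradient descent with
adaptive step halving: a step that raises the energy is rejected and the
step halved, so energy is non-increasing over accepted steps (a property
test).  Coincident nodes make the energy $-\infty$; the energy function
refuses them and instructs the caller to jitter.

## Spectral bisection and the hybrid layout

The hybrid layout partitions the graph before laying it out: the second
eigenpair (Fiedler vector) of the weighted Laplacian $L = D - W$ is found
by power iteration on $\sigma I - L$ with $\sigma$ a Gershgorin bound
($2\max_i L_{ii} + 1$), after projecting out the constant vector; the start
vector is a fixed deterministic sequence, so results are reproducible
without a seed.  Because the sign pattern of the Fiedler vector rarely
splits a graph into *equal* halves, the split is taken at the median
Fiedler value (ties to part A), which guarantees $||A| - |B|| \le 1$.  Each
part is laid out independently by the force model and the two boxes are
placed along the axis of largest extent with a one-diameter gap — the
recombination step is unspecified in the underlying method, so this is the
package's choice.  Disconnected graphs are partitioned into their
components instead.

## Coarsened layout

Multilevel coarsening uses randomized heavy-edge matching (visit order
seeded; each unmatched node merges with its heaviest-edge unmatched
neighbor, ties by id).  Coarsening stops at 3 nodes or when a round shrinks
the graph by less than the rate 0.75 (new/old above 0.75).  The coarsest
graph gets a full force-directed layout; each finer level starts from its
parent's positions plus a small jitter to separate merged pairs and is
refined with 30% of the budget at reduced temperature.

## Simulated-annealing layout with edge cutting

The annealed layout runs the same force iteration through five named phases
— liquid 25%, expansion 25%, cooldown 25%, crunch 10%, simmer 15% of the
budget.  Phases carry temperature/attraction/damping multipliers, but all
default to 1: the defining mechanism is *edge cutting*, and with
`edge_cut = 0` the trajectory must be — and is, bit for bit — identical to
the plain force-directed layout, which is the documented meaning of a zero
edge-cut.  (Distinct per-phase temperatures were tried and dropped for
exactly this reason; users who want a hotter liquid phase can pass their
own phase table.)

Edge cutting suppresses the attraction of *long* edges so densely connected
groups can drift apart.  Which edges count as long is the package's
interpolation: during the middle phases (expansion, cooldown) an edge is
cut when its current length exceeds $\mathrm{mean} + \mathrm{sd}/e$, with
$e$ the edge-cut value in $(0,1]$.  At $e = 1$ anything one standard
deviation above the mean loses attraction (aggressive); small $e$ cuts only
extreme outliers; $e = 0$ never cuts.  A count-based rule (cut the longest
$\lceil e \cdot m \cdot \mathrm{progress}\rceil$ edges) was tried first and
rejected: on dense modular graphs it strips attraction from intra-cluster
edges wholesale, inflating clusters and *reducing* the separation the
mechanism exists to create.  Cutting is disabled in liquid (structure not
yet formed) and in crunch/simmer (so clusters re-tighten internally around
their separated centers).  The default edge-cut is 0.8.

## Semantic levels layout

For multi-type data (genes/diseases/drugs, regulatory tiers) nodes are
assigned to parallel z-planes, by default 7 equidistant levels.
User-supplied assignments are honored verbatim.  The automatic rule is
degree-based: nodes are ranked by decreasing degree (ties by id) and cut
into consecutive bands.  Cut points start at equal-size rank quantiles and
are moved to the nearest degree-tie boundary, so nodes of equal degree
share a level whenever that leaves every level non-empty; when a tie group
spans whole bands (a regular graph), it is split by id order.  This gives
the intuitive outcomes: a star's hub occupies the top level alone, a
regular ring splits into equal bands, and any graph with at least as many
nodes as levels populates every level.  x/y come from a 2D force-directed
pass over the whole graph; z is exactly level × spacing; each level's
induced subgraph is then re-relaxed in its own plane with 20% of the
budget.

## Hemispherical layout

A deterministic layout for clean, bundling-friendly images: nodes are
sorted by decreasing degree (ties by id) and placed along a Fibonacci
spiral on the upper hemisphere, $x = R\cos(\mathrm{lat})\cos(\mathrm{lon})$,
$y = R\sin(\mathrm{lon})\cos(\mathrm{lat})$, $z = R\sin(\mathrm{lat})$.
Rank 0 sits exactly on the pole — the most connected node at the top center
of the hemisphere.  Later ranks descend uniformly in $\sin(\mathrm{lat})$
(uniform in surface area) with a 0.8-cell offset, $\sin(\mathrm{lat}_i) =
1 - (i + 0.8)/n$, longitude advancing by the golden angle.  The offset
keeps rank 1 clear of the pole; measured over a range of $n$, the minimum
great-circle gap stays at about 76% of the equal-area ideal
$\sqrt{2\pi R^2/n}$.  "Equally spaced on a hemisphere" has no closed form
for arbitrary $n$; the spiral is the standard compromise.

## Graph clustering

**Edge-betweenness (Girvan–Newman) sweeps.**  Edge betweenness — the number
of shortest paths crossing an edge, with fractional credit for ties — is
recomputed after every removal, and the edge with the highest value is
removed, subject to two rules: the sweep is budgeted at
$\lceil 0.2\,m\rceil$ removals by default, and any removal that would
isolate a node is skipped (so a star graph loses no edges at all).  Because
"stop when modularity is optimized" and "remove a fixed fraction" are both
legitimate readings of the procedure, the sweep runs the full budget and
reports the modularity-optimal component partition seen anywhere along it,
scored on the *original* graph — satisfying both.  Modularity is
$Q = \sum_c (e_c/m - (d_c/2m)^2)$ with the weighted generalization.

**Markov clustering.**  The column-stochastic transition matrix (weight-1
self-loops added — the standard regularization that guarantees convergence)
is alternately expanded (matrix square) and inflated (entrywise power 2.0,
renormalized, entries below $10^{-5}$ pruned) until the matrix stops
changing ($10^{-6}$, at most 200 iterations; non-convergence returns the
current reading with a warning).  Clusters are the connected components of
the converged flow's support.  Inflation controls granularity: raising it
never decreases the cluster count on the fixture families (a statistical
property test).  Note that inflation 2.0 is a granularity choice, not a
universal optimum — on sparse planted-partition graphs (within-community
edge probability around 0.3) it measurably fragments communities that
inflation 1.4–1.8 recovers exactly, a behavior this implementation shares
with the canonical reference implementation of the algorithm.

**Leading-eigenvector modularity clustering.**  Recursive bisection by the
sign of the leading eigenvector of the (weighted) modularity matrix
$B = W - kk^\top/2m$, restricted to the subgroup with the standard
diagonal correction.  A split is kept only if it raises $Q$ by more than
$10^{-10}$; groups with non-positive leading eigenvalue are indivisible.
Small groups (≤ 400 nodes) use a dense symmetric eigensolver; larger ones
use shifted power iteration with an implicit matrix-vector product, so the
dense matrix is never formed.  Like every greedy modularity maximizer, the
method may split off single boundary nodes of a planted community when
that raises $Q$.

## Cluster layouts

Cluster bubbles: the quotient graph (one node per cluster, inter-cluster
edge weight = count of underlying edges, or their sum) is laid out
force-directed — or with the lin-log model, which pulls strongly
interconnected clusters together — and each cluster's members are arranged
hemispherically on their own transparent bubble.  Bubble radius is
proportional to the cube root of cluster size, scaled so the largest bubble
spans at most 15% of the layout diameter; centers are rescaled outward
until no two bubbles overlap (coincident centers are nudged apart first,
since pure scaling cannot separate them).

The 3D Circos layout slices one hemisphere into contiguous longitude
panels, one per cluster, angular width proportional to cluster size and
summing to exactly 360°.  Slices are ordered by decreasing size (ties by
label), except that the cluster containing the globally most connected
node takes the first slice; within a slice, members descend from near the
pole in decreasing degree order along the slice's own sub-spiral.  The
original description puts "the most connected node at the center of the
hemisphere", which conflicts with per-slice placement when that node's
cluster is not first; the resolution here is per-slice pole proximity plus
first-slice priority for the global maximum.

## Edge bundling

Force-directed edge bundling with the four-factor compatibility product:
angle ($|\cos\theta|$, so antiparallel edges bundle), scale, position, and
mutual visibility.  Pairs above the threshold (default 0.6) attract each
other's subdivision points with magnitude $1/d$; points also feel springs
(stiffness $K/(\ell\,n_{\mathrm{seg}})$, $K = 0.1$) from their neighbors
along the same edge.  Six cycles; subdivisions double each cycle (cycle $c$
runs with $2^c$ interior points), iterations halve from 50, step halves
from $0.04\times$ mean edge length.  Per-point displacement is capped at
the cycle's step size, which tames the $1/d$ singularity as curves meet.
Endpoints never move — they are bit-identical before and after.  Edges with
no compatible partner skip the force loop entirely and stay exactly
straight.  Compatibility is evaluated once, on the original straight
segments, in compiled code (the exhaustive $O(m^2)$ scan is used to
20,000 edges).  When the layout declares a hemisphere constraint, interior
points are radially re-projected onto the sphere after each cycle so
bundles follow the surface.

## Topology statistics

Eight per-node/network measures: degree (and its histogram), neighborhood
connectivity (mean neighbor degree, with the per-degree series), local
clustering coefficients $2e_i/(k_i(k_i-1))$ and their network average,
closeness (reciprocal sum of weighted shortest-path distances within a
node's own component; an optional normalization multiplies by component
size − 1), node betweenness (fractional credit over tied paths), network
diameter and average path length over connected pairs, per-node
shortest-path load (the raw *count* of shortest paths through a node, not
fractional shares), and shared nearest neighbors (reported sparsely, only
for pairs with at least one common neighbor).  Clustering coefficients and
closeness follow the minimum-component rule: only nodes in components with
more than 3 nodes (size ≥ 4) are evaluated, and excluded nodes are blank
(NA), never zero.  The load has no Brandes-style linear accumulation, so it
is computed by an exact $\sigma$-product pair scan and left blank above
2,000 nodes, where the cubic scan would dominate a report — one instance of
the package-wide principle that expensive settings degrade with size.
Reports are written as CSV tables plus PNG distribution charts drawn by the
package's own rasterizer.

## Rendering

The renderer is a deterministic software rasterizer: images are numeric
arrays written through `png::writePNG`, and movies use a built-in GIF89a
encoder (fixed-width 9-bit literal LZW codes with periodic clear codes — a
simple stream every decoder accepts).  The same inputs always produce the
same bytes, which makes image output testable by hashing.  Projection is a
standard look-at transform with perspective or orthographic projection;
points behind the eye are culled with a warning.  Depth is handled by
painter's order with per-glyph sorting — sufficient at these scales, with
the documented limitation that mutually intersecting glyphs have no exact
order.  Nodes draw as shaded sphere impostors (radius ∝ size, scaled by
depth), directed edges get arrowheads, cluster bubbles draw translucently
so the background remains visible through them, and labels are flat 2D text
(a built-in 5×7 bitmap font) with a 1-pixel halo at the projected anchor.
Render quality adapts to size: `adaptive_quality` steps sphere shading,
polyline segment counts and iteration budgets down as $n$ and $m$ grow,
never up.  High resolution is a single large render, capped at 20,000 px
per side.  Rotation movies render frame $f$ at angle
$f\cdot\mathrm{total}/n_{\mathrm{frames}}$ about an axis through the layout
centroid, so a 360° movie wraps seamlessly.

## Synthetic data

The generators give every algorithm a realistic test surface without
downloads, emulating the shapes of typical studies: `make_modular`
(planted-partition communities; cluster-recovery tests use 4 communities of
20 with within/between edge probabilities 0.3/0.01, the regime of sparse
functional modules), `make_scale_free` (preferential attachment, the
hub-dominated degree structure of interactomes; the scale test uses 5,000
nodes with 2 edges per arrival), `make_layered` (gene/disease/drug-style
multi-layer graphs), `make_coordinate_pinned` (a coiled 3D tube with a
distance-decaying correlation matrix whose top-K entries become edges —
the residue-contact shape), and the classic path/star/cycle/clique/barbell
family.  All are seeded and deterministic.  What they do *not* emulate:
real degree-correlation profiles, hierarchical community nesting,
annotation noise, or the heavy-tailed weight distributions of experimental
interaction scores — so passing recovery tests demonstrates algorithmic
correctness on idealized structure, not performance guarantees on real
interactomes.

## Problem sizes and budgets

The test suite runs its property sweeps at deliberately small sizes — 200
random graphs of up to 8 nodes against exhaustive path-enumeration oracles,
spectral checks up to 10 nodes against dense eigensolvers, recovery on 80-
node planted graphs, one 5,000-node end-to-end pipeline — chosen so the
whole suite completes in a few minutes on one CPU while still pinning every
formula to an independent oracle at least once.

## Known limitations

* Layout optimization is local: different seeds give different (mirrored,
  rotated, occasionally differently folded) embeddings of the same graph.
* The exhaustive bundling compatibility scan is quadratic in edge count;
  beyond ~20,000 edges a spatial prefilter would be needed.
* Exact recovery of weak planted partitions is not a guarantee any of the
  three clustering methods can make (see the Markov clustering and
  leading-eigenvector notes above); they are faithful to their standard
  definitions rather than tuned to fixtures.
* GIF output uses fixed-width literal codes: files are larger than a
  dictionary-building LZW would produce, in exchange for simplicity and
  byte determinism.
* SIF conversion drops attributes the format cannot carry (weights,
  colors), with a warning.
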