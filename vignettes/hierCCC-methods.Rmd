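---
title: "Methods: detecting hierarchical structure in cell-cell communication"
author: "hierCCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting hierarchical structure in cell-cell communication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierCCC)
```

# Scope

Cell-cell communication (CCC) is mediated by ligands binding cognate
receptors. Most CCC inference tools score interactions between a single,
predefined partition of cells. hierCCC instead asks two structural
questions: globally, do cell groups form a *hierarchy* of communicating
clusters at multiple resolutions; and locally, do the sets of cells
expressing different ligands (or receptors) *nest* inside one another or
split into disjoint territories, forming signaling trees?

The package answers the first question with multiscale Markov-stability
community detection on a KNN cell graph (`multiscaleCluster()`), and the
second with exact maximal-clique mining of laminar support families
(`detectTrees()`). Everything downstream — marker assignment, interaction
scoring, similarity grouping, the spatial variants — is built on those two
primitives.

# Global hierarchy: Markov stability over a cell graph

## Graph construction

Raw counts are log-normalized: every cell is scaled to the median total
count and `log1p` is applied. Cells embed into a PCA space (default 50
components, computed on the 2000 most variable genes with unit-variance
scaling; ligand-only and receptor-only runs use the expanded subunit gene
lists without a variability filter). Each cell links to its `k = 15` most
cosine-similar neighbors; the directed graph is symmetrized by union,
negative cosine weights are clipped to zero, and self-loops removed.

Random-walk theory requires one irreducible chain, so a disconnected graph
is repaired by adding, for every pair of components, the single
highest-cosine edge between them. Adding one edge per component *pair*
(rather than a spanning tree) matters: when clusters are extremely well
separated, those bridges are the only carriers of the coarse similarity
structure, and a spanning tree alone can push the coarse merging beyond
the scanned Markov times.

## Stability and its optimization

With adjacency $A$, degrees $D$, random-walk Laplacian $L = I - D^{-1}A$
and heat kernel $P(t) = e^{-tL}$, the Markov stability of a partition at
time $t$ is

$$\mathrm{MS}(t) \;=\; \sum_{u,v:\,c_u = c_v} \big(P(t)_{uv} - \pi_v\big),$$

the excess probability that a walker started from the stationary
distribution $\pi$ ($\pi_u = d_u/\sum d$) is found in its own community
after time $t$. Three identities pin the implementation down: the
one-block partition scores exactly 0 at every $t$; singletons score
$n - 1$ at $t = 0$; and for a fixed partition MS is non-increasing in $t$.
All three are asserted in the test suite at machine precision.

$P(t)$ is evaluated exactly through the eigendecomposition of the
symmetric conjugate $D^{-1/2} A D^{-1/2}$, practical to a few thousand
cells per run; a first-order `linearized` fallback ($I - tL$) is available
behind a flag for larger graphs. Because $P(t)$ is not symmetric, Louvain
runs on the symmetrized quality matrix
$Q(t) = (P + P^\top)/2 - (\mathbf{1}\pi^\top + \pi\mathbf{1}^\top)/2$,
whose within-community sums equal MS exactly. $Q$ carries negative entries,
so the optimizer is a generic dense-matrix Louvain (compiled code) rather
than a sparse-graph implementation: greedy node moves with community-sum
bookkeeping, then aggregation, repeated to convergence. Node-move gains are
accepted above a tolerance of $10^{-12}\max|Q|$; scaling the tolerance to
the matrix keeps deep-decay scales from merging on floating-point noise.
At very large $t$ the kernel decays below reconstruction noise
($\max|Q| < 10^{-9}$); every partition then ties at MS $=0$ and the
one-block limit is returned outright. The reported representative is
additionally guarded never to score below the singleton or one-block
partitions.

## Scale selection by variation of information

The scan covers 100 Markov times $10^{l}$, $l$ evenly spaced on
$[-1, 4]$. At each time, 100 Louvain runs (deterministic sub-seeds from
the master seed) yield an ensemble; the highest-MS run is the
representative and the ensemble's mean pairwise variation of information
$\mathrm{VI}_g$ measures optimization robustness. VI uses the standard
definition
$-\sum_{ij} r_{ij}[\log(r_{ij}/p_i) + \log(r_{ij}/q_j)]$
with natural logs; it is a metric on partitions, property-tested against
an independent entropy-based oracle ($H(X) + H(Y) - 2I$).

Representative partitions across the scan form a VI matrix. A *basin* is
a maximal contiguous run of scales whose representatives are pairwise
within `basinTheta` VI of one another; runs at least `basinMinWidth` grid
points wide are kept and each contributes its minimum-$\mathrm{VI}_g$
scale. Defaults are `basinTheta = 0.1` (natural-log VI units) and
`basinMinWidth = 5`: tight enough that different community structures
never share a basin, wide enough to discard one-off partitions that exist
only at isolated grid points. Both are exposed. If no basin qualifies the
single global $\mathrm{VI}_g$ minimum is returned with a warning. Selected
hierarchies are reported coarse to fine; non-nestedness (a fine partition
that does not refine a coarse one, which independent Louvain runs can
produce) is flagged with a warning, never silently repaired.

## Markers, specific pairs, similarity

Multi-subunit units (e.g. `Itga6_Itgb4`) are summarized by the geometric
mean of their subunit columns, so one absent subunit silences the complex.
For every unit and every cluster at every selected scale a one-sided
Wilcoxon rank-sum test (over-expression inside the cluster) is computed;
the normal approximation carries continuity and tie corrections, and an
exact tail (dynamic programming over the tied-rank multiset) switches in
automatically when both groups have at most 12 cells — the same routine
doubles as the test oracle. Each unit is assigned to its global
minimum-$p$ (scale, cluster); ties prefer the coarser scale. Pairs whose
ligand and receptor both pass $p < 10^{-3}$ (raw, per the method;
Benjamini-Hochberg optional) form the specific-interaction list, ranked
by the product of the two $p$-values.

LR pairs and pathways are grouped by a Markov-time-weighted cosine
similarity of their mean-expression profiles over the hierarchy:
$\sum_i w_i \cos(u_i, v_i)$ with $w_i = 1/(\ln \max(T_i, 1) + 1)$. The
weight clamps $T$ at 1 because the unclamped form is singular or negative
below $T = 1$ depending on log base; clamping keeps weights in $(0, 1]$
and preserves the intent of down-weighting coarser scales. The 2D view of
the similarity matrix is a seeded classical MDS embedding followed by
K-means; the embedding is deliberately treated as an opaque plotting
device — tests assert only group recovery on planted similarity blocks,
never coordinates.

## Interaction scoring

Interaction strength between sender and receiver groups is a saturating
mass-action score $xy/(K_h + xy)$ on the mean ligand/receptor unit
expressions, with $K_h = 0.5$. The absolute value is not meaningful and
nothing downstream depends on it; analyses use orderings and interaction
*proportions* (shares of a pair's total strength across group pairs,
summing to 1). Any scoring function with the same signature can be plugged
into `hierarchyInteractions()`, and the detected hierarchical structures
are identical across backends by construction, since scoring happens after
structure detection.

# Local hierarchy: signaling trees

The support of a unit is the set of cells whose (raw-scale) unit
expression exceeds `tau` (default 0, i.e. any expression); supports below
`minCells = 10` cells are dropped, and entities with *identical* supports
are merged into one node (`"a=b"`), since nesting is undefined for equal
sets. Two supports with $m = \min(|s_1|, |s_2|)$ are *disjoint* when
$|s_1 \cap s_2| \le \varepsilon m$ and *inclusive* when
$|s_1 \cap s_2| \ge (1 - \varepsilon) m$ with unequal sizes; at the
default $\varepsilon = 0$ these are exact set relations. Entities whose
supports are disjoint-or-inclusive are connected in a relation graph; a
set of entities that is pairwise so connected is exactly a laminar family,
i.e. a forest under inclusion. Maximal such families are the maximal
cliques of the relation graph, enumerated exactly by Bron-Kerbosch with
pivoting. Each clique decomposes into rooted trees by the Hasse rule
(parent = smallest strict superset); components below `minNodes = 2` are
filtered. With $\varepsilon > 0$ laminarity can break inside a clique;
offending children are detached to new roots with a warning rather than
fabricating an inclusion.

The equivalence "maximal clique = maximal laminar subfamily" is the
load-bearing claim, so the whole pipeline is compared against brute-force
enumeration of maximal laminar subfamilies over all entity subsets (and an
independent Hasse construction) on hundreds of random support matrices.
The clique enumerator is separately cross-checked against igraph.

Trees are detected for ligand units, receptor units, or per-database-pair
ligand-receptor support unions (`lr_union`, one entity per interaction).
Per-pair unions were chosen over per-pathway unions because the union
entity then answers a concrete question — which cells participate in this
interaction on either side. Ligand and receptor trees sharing at least one
database interaction are paired for cross-tree analysis, and entity
importance is ranked by tree-membership frequency.

# Spatial variants

For spot-based data, scaled coordinates (min-max to $[0,1]$ per axis,
multiplied by `spatialWeight`, default 1 = plain concatenation) are
appended to the PCA embedding before graph construction; weight 0
reproduces the nonspatial run exactly, and large weights drive clustering
toward spatial tessellation. For tree detection, a unit's support can be
restricted to spots that have a cognate partner-expressing neighbor within
radius `r` (exact Euclidean neighborhoods via grid bucketing; default
`r` = twice the 5th percentile of nearest-neighbor distances, exposed
because capture radii differ across platforms). The filter is contractive
and monotone in `r`, both asserted as properties. Spatial coherence of a
labeling is quantified by a permutation z-score of same-label neighbor
pairs.

# Synthetic data generators

Two generators define the validation conditions; they are first-class,
tested code.

**Hierarchical counts.** 1000 cells split evenly into 2/4/8 perfectly
nested clusters; 10000 genes of which 1000 are markers. Marker totals per
scale are 400/400/200 (200 per cluster at the coarsest scale, 100 at the
middle, 25 at the finest; the finest per-cluster count follows from the
scale totals and the 1000-marker budget). A marker's in-cluster mean is
its fold change times the out-cluster mean, tied to the gene's base mean
$m$ by $\rho\mu_\text{in} + (1-\rho)\mu_\text{out} = m$ where $\rho$ is
the cluster fraction. Counts are negative binomial with dispersion 0.1
(variance $\mu + 0.1\mu^2$). Base means come from a reference profile:
the self-contained `builtin` profile draws means from
log-normal(1, 1), markers from its top-20% stratum and non-markers from
the lower 80%, with fold changes (3, 4, 5) from coarsest to finest scale —
stronger effects for the smaller, finer clusters, chosen once so the
planted structure is detectable but not trivial. A `pbmc3k` profile can
instead derive means and fold changes from a local copy of the public 10x
PBMC-3k matrix plus a cell-label CSV (median-total normalization, top-20%
marker stratum, per-scale median one-vs-rest fold changes); without those
local files it stops with a pointer to the source. The builtin profile is
documented as *not* that dataset's parameterization.

**Planted trees.** 1000 cells, 100 binary genes; 15 structured genes
realize five laminar trees (chains and root-with-disjoint-children shapes,
three genes each) on disjoint 200-cell blocks, and each of the remaining
85 background genes is expressed in 500 uniformly drawn cells. Background
supports intersect everything partially with overwhelming probability, so
they join no clique; the construction makes recovery a sharp correctness
test of the relation/clique/forest machinery rather than a statistical
one.

What the generators do *not* emulate: library-size variation beyond the NB
model, doublets, ambient RNA, batch effects, dropout beyond NB zeros, or
continuous (trajectory-like) population structure. Passing the validation
therefore demonstrates correctness of the machinery under the stated
model, not robustness to every artifact of real data.

# Validation experiments and problem sizes

The package's acceptance checks (in `tests/testthat/test-acceptance.R`
and recomputed by `scripts/acceptance.R`) run:

- planted-tree recovery over 100 simulation trials — all five trees must
  be present in the output in every trial;
- hierarchy recovery on the builtin-profile count simulation for seeds
  0-4 — at least three selected scales, ARI $\ge 0.90$ against the
  2-cluster labeling and $\ge 0.95$ against the 4- and 8-cluster
  labelings;
- the laminar/clique brute-force equivalence on 200 random support
  matrices (up to 12 entities, 30 cells);
- the analytic MS/VI identities and the monotonicity properties above;
- byte-identical outputs for identical configs and seeds.

These runs keep the generators at the study conditions (1000 cells,
10000 genes; 1000 cells, 100 genes) and use the full 100-point Markov-time
grid with 25 Louvain runs per scale — the package default remains 100
runs; 25 is the suite's choice and, on these simulations, the selected
scales are identical. On a single desktop core the hierarchy run takes
roughly a minute per seed.

# Known limitations

- Exact spectral evaluation of $P(t)$ is dense: memory and time scale as
  $n^2$-$n^3$. Beyond a few thousand cells, subsample (as the validation
  experiments do) or use the linearized kernel.
- Scale selection reports what the scan found; it does not enforce strict
  nestedness across scales.
- The mass-action score ignores cofactors, agonists/antagonists and
  receptor competition; it is a ranking device, not a binding model.
- Tree detection at $\varepsilon = 0$ is brittle to single stray cells in
  a support (a one-cell overlap voids disjointness); raising
  $\varepsilon$ trades that brittleness for possible intransitivity,
  which is repaired conservatively.
- The 2D similarity embedding is for orientation only; distances in that
  plane carry no inferential weight.
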