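---
title: "Flow-based network analysis of a retinal connectome sample: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-based network analysis of a retinal connectome sample}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Serial block-face electron microscopy of a ~0.1 mm piece of the mouse
retina's inner plexiform layer yields a list of hundreds of thousands of
cell-to-cell membrane contacts: for each contact, the two cell IDs, the
apposed area in square micrometres, and the contact centroid in the sample
volume. Contact area is only a proxy for a synapse -- at 0.08 um^2 the
odds of a true synaptic contact are about even -- so turning this list into
a usable neuronal network requires careful filtering, pooling of
multiple contacts per cell pair, and correction of listing artifacts.
`retinaflow` implements that ingestion, the network statistics used to
characterise such samples, a flow-based (map equation) and several
structural module decompositions, spatial analyses of the excised sample's
edge artifacts and of module geometry in the retinal plane, graph layouts,
and circuit extraction around high-flow neurons. A synthetic-data
generator with known ground truth makes every stage testable without any
external download.

The workflow lives in `analysis/01_simulate.R` ... `analysis/07_circuits.R`;
each script is a thin driver over package functions, so the same code paths
are exercised by the test suite and by `scripts/acceptance.R`.

## Building the graph from contacts

**Filtering.** `filter_contacts()` retains contacts with area at or above a
threshold. The comparison is inclusive (`>=`) because the thresholds are
calibrated as probability points (50% synapse probability at 0.08 um^2),
so a boundary contact is as likely a synapse as not; a `strict` flag is
available. Two thresholds matter: the 0.08 um^2 synapse-probability floor,
and the more conservative 0.16 um^2 value that defines *unit link weight*.

**Aggregation.** `aggregate_links()` pools records by unordered pair
`(i, j)`, sums the surviving contact areas and divides by the unit-weight
threshold, so link weights are real multiples of that threshold (weight 2 =
twice the threshold area). They are stored at full precision; reports round
only for display. Two conventions are implemented because the provenance of
the 0.16 um^2 step is ambiguous: `per_contact` (default) removes individual
contacts below the threshold before summation -- every retained link then
has weight >= 1 by construction -- while `per_pair_total` sums all contacts
above the 0.08 floor and keeps pairs whose total reaches the threshold.
`per_contact` link sets are always a subset of `per_pair_total` sets at the
same threshold, which is tested as an invariant.

**Over-counting correction.** Raw lists record some contacts twice, once
as `i -> j` and once as `j -> i`. Summing both would double those areas, so
aggregation first removes *exact duplicates*: records identical in
unordered pair, area and coordinates. Genuinely distinct contacts that
happen to be listed in opposite orders have distinct coordinates and are
both kept. On synthetic data, where duplicates are planted with a known
rate, the correction is exact: a sample with duplicates aggregates to the
same matrix as its duplicate-free twin (tested bit-for-bit).

**The catalog.** Neurons are numbered sequentially by type (ganglion cells
1-36, near-field amacrines 37-226, wide-field amacrines 227-389 with the
Off- and On-starburst ranges 260-274 and 358-370 nested inside, cone
bipolars 390-696, rod bipolars 697-840, one-of-a-kind cells 841-950).
`load_cell_catalog()` validates that the configured ranges tile the ID
space without gaps or overlap. Glia carry IDs beyond the neurons and are
dropped at the catalog-restriction step with a logged count.

## Network measures: conventions

* Weighted degree (strength) is the adjacency row sum `k_i = sum_j A(i, j)`.
* Betweenness (node and edge) is *unnormalized* and counts unordered
  source-target pairs with endpoints excluded, sharing credit equally among
  tied geodesics. This is the convention under which a 3-node path gives
  nBC(b) = 1 and eBC(a, b) = 2, and it reproduces the magnitude of
  published per-node values on 950-node samples (means in the hundreds to
  thousands). Normalization is available as a flag.
* On the weighted network, traversal length of a link is the inverse of its
  weight, so heavy (large-area) links are short. This is a convention, not
  a derived fact; ranked outputs should be compared by rank across
  conventions, and the `unit` length rule is available.
* The shortest-path census runs on the unweighted topology and counts
  ordered pairs; disconnected pairs are tallied separately, and percentages
  are quoted over connected pairs.
* Betweenness on graphs of up to 12 nodes is tested against an exhaustive
  geodesic-enumeration oracle (Floyd-Warshall distances plus depth-first
  enumeration of all tied geodesics), with edge weights drawn from powers
  of two so that tie detection is exact in floating point for the
  implementation and the oracle alike.

## Flow-based decomposition (the map equation)

A random walker on the undirected weighted graph visits node `i` with
stationary probability `p_i = k_i / sum_j k_j`; no teleportation is needed
because the walk is undirected and the zero-degree nodes are excluded from
the walk (they are carried as singleton modules with zero flow). For a
partition M of the nodes into modules, the *two-level map equation* scores
the expected description length, in bits per step, of the walk under a
two-level Huffman coding: one index codebook to announce module entries,
one codebook per module for within-module moves and exits,

    L(M) = q H(Q) + sum_m (p_m + q_m) H(P_m),

where `q_m` is the stationary flow on links leaving module m, `q = sum q_m`,
`p_m` the total visit rate of m's members, `H(Q)` the entropy of the
normalized exit flows and `H(P_m)` the entropy of module m's exit and visit
rates. All logarithms are base 2 -- codelengths are bits. For a single
module the expression collapses to the visit-rate entropy
`-sum_i p_i log2 p_i`, which anchors the closed-form tests (a 4-cycle in
one module costs exactly 2 bits; two disjoint dyads split in two cost
exactly 1 bit).

`infomap_partition()` minimises L with a greedy Louvain-style search,
written in C++: repeated sweeps of single-node moves (each move evaluated
by an O(neighbouring modules) codelength delta), followed by aggregation of
modules into supernodes, iterated to a fixed point; the best of `trials`
seeded restarts is kept. The restart RNG is a private Mersenne Twister with
a hand-rolled Fisher-Yates shuffle, so results are reproducible
bit-for-bit from `(graph, seed, trials)` across platforms. On 8-node random
graphs the greedy optimum matches exhaustive enumeration over all 4140 set
partitions in at least 95 of 100 instances (an acceptance property), and on
planted two-clique graphs it recovers the planted split exactly.

Modules are relabeled in decreasing order of internal flow, ties broken by
smallest member ID; zero-degree nodes become trailing singleton modules. A
module is reported as *non-trivial* when it has more than 15 members or
hosts more than 1% of the flow -- the operational definition used in the
module summary table.

## Structural decompositions

For comparison the package wraps the standard structural methods behind the
same partition container: Newman's modularity Q (`modularity_Q()`, with the
degree-preserving null), divisive edge-betweenness removal
(`girvan_newman()`, cutting the dendrogram at a target module count),
fast-greedy agglomeration (`cnm_agglomerative()`, maximum-Q cut), and
spectral k-means (`spectral_partition()`) on either the graph Laplacian
(eigenvectors of the smallest nonzero eigenvalues) or the modularity matrix
(positive-eigenvalue eigenvectors only). Spectral k-means uses 20 seeded
restarts and, when no `k` is given, scans k = 2..20 and returns the
maximum-Q choice along with the whole scan. The participation coefficient
`P_i = 1 - sum_m (k_im / k_i)^2` quantifies how much a node's strength
spreads across modules.

## Spatial analyses

**Edge vs core.** An excised sample loses every link that crossed the cut,
so neurons near the boundary have systematically fewer links. Neurons whose
in-plane soma coordinate lies within a margin (default 10 um) of any of the
four lateral boundaries are classed `edge`, the rest `core`, and zone means
of degree and betweenness are compared. The analysis plane and its two axes
are configuration, never hard-coded, because the published edge analysis
quotes an 80 x 114 um plane while the volume is 132 x 114 x 80 um; the
synthetic workflow passes its own box's lateral extents.

**Module mosaic.** For a chosen cell class (the cone bipolars in the
figures), each module's member somata define a 2D convex hull; the package
reports hull areas, centroids, all pairwise hull-overlap areas (computed by
a Sutherland-Hodgman convex clip written here, as no installed package
provides polygon intersection) and a *tiling score*: total pairwise overlap
area divided by total hull area. A clean mosaic scores near zero. The
tiling score is this package's operationalization -- the term "tiled
mosaic" has no standard formula.

## Layouts

`sde_layout()` is classical multidimensional scaling of the hop-distance
matrix: double-centre `-D^2/2`, take the leading positive eigenpairs, scale
eigenvectors by the square roots of their eigenvalues. This solves the
spectral (strain) problem, which captures the global
distances-proportional-to-geodesics objective; the residual stress
`sum (||x_i - x_j|| - D_ij)^2` is reported for audit. When `D` is exactly
Euclidean-realizable the embedding reproduces it with stress below 1e-8
(tested); on generic graph geodesics classical scaling trails an iterative
stress minimizer (SMACOF) by a bounded factor, which the tests document
rather than hide. Determinism: eigenvector signs are fixed by making each
axis's largest-magnitude coordinate positive. Nodes outside the largest
component are placed on a display ring at 1.2x the embedding radius and
flagged `in_embedding = FALSE`. The anatomical layout instead assigns one
axis by cell class (bipolars at 0.1 through ganglion cells at 0.9,
configurable) and uses soma plane coordinates for the others.

`strong_link_subgraph()` keeps exactly the links incident to a focus set
whose weight strictly exceeds a bound (figure captions like "(>10)" are
strict), a monotone operation in the bound.

## Circuit reports

`circuit_report()` partitions a focus neuron's adjacency row by partner
class: strong links (weight > 10 by default, sorted descending), candidate
feedback links (bipolar partners at weight <= 2 -- weak amacrine-to-bipolar
links being the anatomically plausible gain-control return path; no
directionality is claimed), and Off/On tallies of cone-bipolar inputs. The
Off/On assignment of cBC subtypes is configuration, not code
(`default_off_on_map()`: types 1-4 Off; 5A/5R/5X, 6-9 and XBC On, the
standard stratification convention), and unmapped subtypes are counted as
unclassified with a warning.

## The synthetic generator: what it emulates, and what not

`generate_sample()` draws a typed neuron population (the canonical class
counts: 36 GC, 190 NFac, 163 WFac including 15 Off-SAC and 13 On-SAC, 307
cBC, 144 rBC, 110 other, plus 173 glia) uniformly in a 132 x 114 x 80 um
box, plants `M = 10` module centres in the retinal plane with a
minimum-separation rule, assigns each neuron to its nearest centre
(a Voronoi mosaic), and draws contact counts per unordered pair from a
Poisson law with rate

    contact_rate * exp(-d / lambda) * rho^[same module],

`d` the lateral soma distance. Contact areas are lognormal; each contact is
listed once in random orientation and duplicated in reversed order with
probability 0.14 (the over-counting artifact); contacts whose jittered
centroid falls outside the box are moved to a truncated-link list.
`truncation_experiment()` instead grows the box by a halo equal to the
excision margin, draws one sample there, and removes everything outside the
core box -- the paired full/excised samples with known loss that the
edge-artifact analyses need.

Parameter defaults, with units and rationale:

| parameter | default | meaning / why |
|---|---|---|
| `box` | 132 x 114 x 80 um | the study volume |
| class counts | per canonical ID ranges | the study's composition |
| `n_modules` | 10 | matches the number of non-trivial flow modules reported for the real sample |
| `lambda` | 10 um | lateral contact-rate decay; the scale of local dendritic overlap, and jointly calibrated (below) |
| `rho` | 8 | within/between module rate ratio; strong enough that planted modules are recoverable |
| `contact_rate` | 1.0 | Poisson mean at zero distance, between modules |
| `area_meanlog`, `area_sdlog` | -2.753, 1.0 | lognormal areas; chosen analytically so P(area >= 0.08) = 0.41, the retention fraction the real list shows at the synapse threshold |
| `dup_frac` | 0.14 | reversed-duplicate listing rate, per contact (the simplest mechanism consistent with ~14% over-counting) |
| `contact_jitter` | 2 um | contact centroid scatter around the soma midpoint |
| `glia_rate_factor` | 0.1 | glia contact everything, but weakly |

`lambda`, `rho` and `contact_rate` were calibrated once, at design time,
against the generator's emulation goals -- ~41% of contacts above 0.08
um^2, an edge-vs-core weighted-degree deficit of 20-25% under a 10 um
excision, and a recoverable 10-module mosaic -- and then frozen. The
sample is deliberately *sparser* than the real one (about 19 links per
neuron rather than ~100): link density multiplies runtimes but adds nothing
to the properties under test, and all tests and the acceptance script use
these defaults as the stated problem size.

Two experiment-design notes. First, the relative edge-vs-core gap grows
with the link range `lambda` only while `lambda` is small against the core
depth and the excised halo covers the kernel's reach; long kernels deplete
the core too and *narrow* the relative gap. The monotonicity test therefore
uses a 200 x 200 um plane, a 30 um halo, a flat module structure and link
counts (not heavy-tailed weights). Second, Voronoi cells of random centres
are irregular, so a module's hull centroid can sit 10-20 um from its
planted centre; the ground-truth property is association (each hull
centroid is nearest its own centre, which lies inside the hull), not a
fixed distance.

What the generator does **not** emulate: neurite morphology (contacts
attach to soma midpoints, not arbors), depth stratification of the inner
plexiform layer, realistic per-class connectivity rules (all classes share
one kernel), heavy-tailed degree structure beyond what lognormal areas
induce, and the real sample's link density. Passing tests therefore
demonstrate that the *pipeline* is correct under known ground truth -- not
that the biological conclusions drawn from any particular real sample
would be reproduced. Analyses that depend on the real 950-neuron matrix
(its exact link count, degree means, path census and module table) run only
when that supplementary file is supplied via
`options(retinaflow.s1_adjacency = ...)`.

## Numerical choices and degenerate inputs

* Adjacency symmetry is enforced within 1e-9 (worst offending pair
  reported); the stored matrix is the symmetrised average, diagonal zeroed.
* Map-equation terms use `x log2 x = 0` at zero; greedy moves require an
  improvement of at least 1e-12 to guard against round-off cycling.
* All orderings break ties toward the smaller node ID, making rankings and
  module labels deterministic.
* Full-precision (`%.17g`) text I/O makes write/read round trips bitwise.
* Degenerate inputs: all-zero graphs error on flow quantities; modules with
  fewer than 3 located members are flagged `degenerate` with no hull; an
  unreachable divisive target returns the best achieved split with a
  warning; graphs whose distance matrix has fewer positive eigenvalues than
  requested dimensions return a reduced-dimension layout with a warning.

## Known limitations

* The map equation is two-level only; hierarchical decompositions are out
  of scope.
* Links are undirected throughout -- synaptic direction is not inferred,
  and "feedback" names a weight band plus partner class, not a causal
  claim.
* Weighted-betweenness conventions (inverse-weight lengths) are not
  universal; compare ranked outputs across conventions by rank.
* The divisive (edge-betweenness) method recomputes betweenness after each
  removal and is quadratic-plus in practice; it is intended for small
  graphs and method comparisons, not for the full sample.
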