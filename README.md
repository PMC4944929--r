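# retinaflow

Network analysis of cellular-resolution retinal connectome samples, built
around flow-based module detection.

Electron-microscopy reconstructions of retinal tissue yield raw lists of
cell-to-cell membrane contacts — `(cell_i, cell_j, area in um^2, x, y, z)` —
rather than networks. `retinaflow` is for researchers who want to go from
such a contact list to a defensible weighted synaptic graph and its
analysis: centrality and path statistics, modular decomposition, spatial
artifact quantification, layouts and candidate circuits. Every stage is
testable against a synthetic retina-like sample with known ground truth, so
no external data are required to validate the pipeline.

## What it computes

**Graph construction.** Contacts are filtered at a synapse-probability
area threshold (0.08 um^2), pooled by unordered cell pair with exact
reversed-duplicate listings removed (the "over-counting" artifact of raw
contact lists), summed, and expressed as weights `A(i, j)` in multiples of
a conservative unit-weight threshold (0.16 um^2). The result is a
symmetric weighted adjacency over the neuron catalog (glia dropped, class
ID ranges validated).

**Network statistics.** Weighted degree `k_i = Σ_j A(i,j)`; node and edge
betweenness centrality (unnormalized, unordered-pair counts, endpoints
excluded, tied geodesics share credit; weighted traversal length
`ℓ_ij = 1/A(i,j)`); the shortest-path census; degree distributions.

**Flow modules (the core method).** A random walker visits node *i* with
stationary probability `p_i = k_i / Σ_j k_j`. A partition M of the nodes is
scored by the two-level map equation,

    L(M) = q H(Q) + Σ_m (p_m + q_m) H(P_m)        [bits per step]

(`q_m` = flow leaving module *m*, `p_m` = member visit rates, `H(·)` =
entropies of the normalized exit and within-module flows), and
`infomap_partition()` minimizes L by a seeded greedy node-move /
module-aggregation search implemented in C++. Structural alternatives
(Newman's Q, Girvan–Newman divisive, fast-greedy agglomerative, spectral
k-means on Laplacian or modularity matrix) and participation coefficients
are included for comparison.

**Spatial analyses.** Edge-vs-core comparisons quantify the degree deficit
of neurons near the excised sample boundary; module mosaic geometry
(convex hulls, centroids, pairwise hull overlaps, a tiling score) describes
how modules tile the retinal plane.

**Layouts and circuits.** Classical scaling of hop distances (spectral
distance embedding), anatomically layered layouts, strong-link subgraphs
around focus neurons, and per-neuron circuit reports (strong partners by
cell class, weak bipolar feedback candidates, Off/On input tallies).

## Worked example

```r
library(retinaflow)

sample  <- generate_sample(generator_params(), seed = 1)
contacts <- restrict_to_catalog(sample$contacts, sample$catalog)
graph   <- aggregate_links(contacts, threshold = 0.16,
                           node_ids = sample$catalog$id)
graph
#> <weighted_graph> 950 nodes, 10906 links, threshold 0.16 um^2

res <- infomap_partition(graph, seed = 1, trials = 10)
res$codelength
#> [1] 7.236687
head(module_flow_table(res$flow, res$partition, sample$catalog), 5)
#>   module      flow n_members key_classes nontrivial
#> 1      1 0.1527768       135   cBC, NFac       TRUE
#> 2      2 0.1480913       131   cBC, NFac       TRUE
#> 3      3 0.1325112       125   cBC, NFac       TRUE
#> 4      4 0.1281832       111   cBC, NFac       TRUE
#> 5      5 0.1044146        93    cBC, rBC       TRUE

partition_similarity(res$partition, sample$truth)
#> [1] 1
```

The generated sample has 950 neurons and ~11k links; describing a random
walk on it with the returned modular map costs 7.24 bits per step, the
modules are listed by decreasing signal flow with their member counts and
leading cell classes, and the planted ground-truth modules are recovered
exactly (adjusted Rand index 1).

The excision artifact, with a known-loss paired experiment:

```r
tr  <- truncation_experiment(generator_params(), margin = 10, seed = 1)
rep <- edge_core_deficit(tr$truncated, margin = 10)
rep$deficit_pct[["k"]]
#> [1] 20.54085
```

Neurons within 10 um of the cut boundary average ~21% lower weighted
degree than core neurons — links they had to partners outside the box were
lost with the excision.

The full workflow over a simulated raw sample is in `analysis/` (numbered
scripts `01_simulate.R` … `07_circuits.R`); each writes its tables and
figures under `results/`. The methods vignette
(`vignettes/retina-connectome-workflow.Rmd`) documents the models,
conventions, generator calibration and limitations.

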