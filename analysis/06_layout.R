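#!/usr/bin/env Rscript
# Stage 6: layouts. Spectral distance embedding (classical scaling of the
# hop-distance matrix) for an abstract view, the anatomically layered
# layout (bipolar cells innermost, ganglion cells outermost), and a
# strong-link view around the highest-flow neurons.

library(retinaflow)

graph <- read_adjacency("results/adjacency.csv", threshold = 0.16)
catalog <- structure(utils::read.csv("results/sample/cells.csv"),
                     class = c("cell_catalog", "data.frame"))
membership <- read_membership("results/membership.txt")

D <- graph_distances(graph)
lay <- sde_layout(D, dims = 3)
message(sprintf("SDE layout: %d nodes embedded, stress %.1f",
                sum(lay$coords$in_embedding), lay$stress))
utils::write.csv(lay$coords, "results/sde_coords.csv", row.names = FALSE)

anat <- anatomical_layout(catalog)
utils::write.csv(anat, "results/anatomical_coords.csv", row.names = FALSE)

## strong-link view around the top-10 flow nodes
p <- stationary_flow(graph)
top_flow <- as.integer(names(sort(p, decreasing = TRUE)))[1:10]
sub <- strong_link_subgraph(graph, top_flow, weight_min = 10)
message(sprintf("top-10-flow strong-link subgraph: %d nodes, %d links (> 10)",
                length(sub$ids), attr(sub, "n_links")))
render_view(lay$coords, sub, membership, catalog,
            file = "results/fig_strong_links.png")
message("strong-link figure written to results/fig_strong_links.png")
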