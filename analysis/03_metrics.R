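#!/usr/bin/env Rscript
# Stage 3: basic network features -- degree and strength, node and edge
# betweenness centrality on the weighted network (link length = 1/weight),
# the shortest-path census over the unweighted topology, and the degree
# distribution.

library(retinaflow)

graph <- read_adjacency("results/adjacency.csv", threshold = 0.16)

met <- weighted_degree(graph)
bc <- betweenness_centrality(graph, use_weights = TRUE)
nodes <- merge(met, bc$nodes, by = "node")
utils::write.csv(nodes, "results/node_metrics.csv", row.names = FALSE)
utils::write.csv(bc$edges, "results/edge_metrics.csv", row.names = FALSE)

message(sprintf("mean weighted degree: %.1f; zero-degree neurons: %d",
                mean(met$k), sum(met$k == 0)))

cen <- shortest_path_census(graph)
print(cen$census)
message(sprintf("connected ordered pairs: %d; disconnected: %d",
                cen$n_connected_pairs, cen$n_disconnected_pairs))

h <- degree_histogram(met, binning = "log")
message(sprintf("log-log degree-frequency slope: %.2f (zero-degree: %d)",
                degree_loglog_slope(h), attr(h, "n_zero")))
utils::write.csv(h, "results/degree_histogram.csv", row.names = FALSE)
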