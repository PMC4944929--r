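#!/usr/bin/env Rscript
# Stage 7: candidate circuits around high-flow neurons -- strong partners
# grouped by cell class, weak bipolar "feedback" candidates, Off/On input
# tallies -- plus the cross-measure ranking table (flow vs betweenness vs
# weighted degree).

library(retinaflow)

graph <- read_adjacency("results/adjacency.csv", threshold = 0.16)
catalog <- structure(utils::read.csv("results/sample/cells.csv"),
                     class = c("cell_catalog", "data.frame"))
nodes <- utils::read.csv("results/node_metrics.csv")

p <- stationary_flow(graph)
rk <- rank_nodes(p, nodes, top_k = 10)
print(rk$table)
message(sprintf("top-10 overlap: flow/nBC %d, flow/degree %d, all three %d",
                rk$overlap[["flow_nbc"]], rk$overlap[["flow_degree"]],
                rk$overlap[["all_three"]]))
utils::write.csv(rk$table, "results/rankings.csv", row.names = FALSE)

## circuit reports for the two highest-flow amacrine cells
cls <- cell_class_of(catalog, as.integer(names(p)), prefer_subclass = FALSE)
ac_ids <- as.integer(names(p))[cls %in% c("NFac", "WFac")]
top_ac <- ac_ids[order(-p[as.character(ac_ids)])][1:2]
for (focus in top_ac) {
  rep <- circuit_report(graph, catalog, focus = focus,
                        strong_min = 10, feedback_max = 2)
  print(rep)
  utils::write.csv(rep$partners,
                   sprintf("results/circuit_%d.csv", focus),
                   row.names = FALSE)
}
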