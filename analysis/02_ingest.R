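#!/usr/bin/env Rscript
# Stage 2: ingest the raw contact list -- drop glia records, filter by
# contact area, pool reversed listings per unordered cell pair (removing
# exact duplicates, the over-counting correction), and aggregate to the
# weighted adjacency matrix at the conservative 0.16 um^2 unit-weight
# threshold.

library(retinaflow)

contacts <- read_contact_list("results/sample/contacts.csv")
catalog <- structure(utils::read.csv("results/sample/cells.csv"),
                     class = c("cell_catalog", "data.frame"))

contacts <- restrict_to_catalog(contacts, catalog)
message(sprintf("retained %d neuron-neuron contact listings", nrow(contacts)))
message(sprintf("fraction above the 0.08 um^2 synapse threshold: %.1f%%",
                100 * mean(contacts$area >= 0.08)))

graph <- aggregate_links(contacts, threshold = 0.16,
                         filter_mode = "per_contact",
                         node_ids = catalog$id)
agg <- attr(graph, "aggregation")
message(sprintf("duplicate listings removed: %d", agg$duplicates_removed))
message(sprintf("links: %d (density %.1f%% of all pairs)", agg$links,
                100 * agg$links / (nrow(catalog) * (nrow(catalog) - 1) / 2)))

write_adjacency(graph, "results/adjacency.csv")
message("adjacency written to results/adjacency.csv")
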