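#!/usr/bin/env Rscript
# Bin the occurrences onto the 10-degree hexagonal grid per stage and build
# the weighted bipartite multilayer network (links w = n/N between genera
# and spatiotemporal cells). For stage-merge handling on a real timescale,
# see merge_map_for_stages(); the synthetic timescale needs no merging.

library(fossilflows)

ts <- read_timescale("results/timescale.tsv")
occ <- read_occurrences("results/occurrences.tsv", ts)
agg <- aggregate_occurrences(occ, hex_grid())
write_agg_counts(agg, "results/aggregated_counts.tsv")

net <- assemble_network(agg)
write_multilayer_network(net, "results/network.net")
print(net)
cat(sprintf("occupied spatiotemporal cells: %d\n",
            nrow(unique(agg[, .(stage_index, cell_id)]))))
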