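#!/usr/bin/env Rscript
# Robustness of the module structure to the relax rate: cluster the network
# over a range of rates and compare each solution to the r = 0.25 reference
# by mean best-match Jaccard similarity over major modules.

library(fossilflows)

ts <- read_timescale("results/timescale.tsv")
occ <- read_occurrences("results/occurrences.tsv", ts)
net <- assemble_network(aggregate_occurrences(occ))

sweep <- relax_rate_sweep(net, c(0.05, 0.15, 0.25, 0.35, 0.5),
                          cluster_params(num_trials = 10L, seed = 1L))
data.table::fwrite(sweep, "results/relax_rate_sweep.tsv", sep = "\t")
print(sweep)
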