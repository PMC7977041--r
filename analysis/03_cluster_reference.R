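#!/usr/bin/env Rscript
# Reference clustering of the assembled network with the multilayer map
# equation (relax rate 0.25, relax limit 1). Writes the partition tree, the
# per-trial codelengths and the dominance timeline.

library(fossilflows)

net <- read_multilayer_network("results/network.net")
params <- cluster_params(num_trials = 20L, seed = 1L)
flow <- stationary_flow(net, params)
part <- ml_cluster(net, params, flow = flow)
print(part)

write_partition_tree(part, "results/reference_partition.tree")
data.table::fwrite(
  data.table::data.table(trial = seq_along(attr(part, "trial_codelengths")),
                         codelength = attr(part, "trial_codelengths")),
  "results/trial_codelengths.tsv", sep = "\t")

tl <- dominance_timeline(part)
data.table::fwrite(tl$shares, "results/dominance_shares.tsv", sep = "\t")
data.table::fwrite(tl$transitions, "results/transitions.tsv", sep = "\t")

majors <- top_modules(part)
cat(sprintf("major modules (>=1%% flow): %s\n", paste(majors, collapse = ", ")))
print(tl)
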