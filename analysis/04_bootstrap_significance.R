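#!/usr/bin/env Rscript
# Parametric bootstrap of the link weights (truncated Poisson on the
# occurrence counts), re-clustering of every replicate, and the module
# support (P05/P07) and per-stage significance statistics.

library(fossilflows)

ts <- read_timescale("results/timescale.tsv")
occ <- read_occurrences("results/occurrences.tsv", ts)
agg <- aggregate_occurrences(occ)
net <- assemble_network(agg)
params <- cluster_params(num_trials = 20L, seed = 1L)
part <- ml_cluster(net, params)

boot <- bootstrap_ensemble(agg, params = cluster_params(num_trials = 10L),
                           replicates = 25L, seed = 100L,
                           dir = "results/bootstrap")
sup <- module_support(part, boot)
sig <- per_layer_significance(part, boot)
data.table::fwrite(sup, "results/module_support.tsv", sep = "\t")
data.table::fwrite(sig, "results/per_stage_significance.tsv", sep = "\t")
print(sup)
cat(sprintf("per-stage significance: min %.2f (layer %d), median %.2f\n",
            min(sig$median_probability),
            sig$layer[which.min(sig$median_probability)],
            stats::median(sig$median_probability)))
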