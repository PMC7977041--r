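#!/usr/bin/env Rscript
# Partition-level statistics: AMI of the module structure against the
# timescale units, taxon sharing between major modules (Jaccard and
# Sorensen), latitudinal band richness, and the alluvial overlap between the
# reference solution and a bootstrap replicate.

library(fossilflows)

ts <- read_timescale("results/timescale.tsv")
occ <- read_occurrences("results/occurrences.tsv", ts)
agg <- aggregate_occurrences(occ)
net <- assemble_network(agg)
params <- cluster_params(num_trials = 20L, seed = 1L)
part <- ml_cluster(net, params)

ami_era <- ami(part$top, layer_labels(part, ts, level = "era"))
ami_period <- ami(part$top, layer_labels(part, ts, level = "period"))
cat(sprintf("AMI of state-node modules vs eras: %.3f, vs periods: %.3f\n",
            ami_era, ami_period))

majors <- top_modules(part)
jac <- outer(majors, majors, Vectorize(function(a, b) taxon_jaccard(part, a, b)))
dimnames(jac) <- list(majors, majors)
cat("taxon Jaccard between major modules:\n")
print(round(jac, 3))
bsor <- outer(majors, majors, Vectorize(function(a, b)
  sorensen_dissimilarity(module_genera(part, a), module_genera(part, b))))
dimnames(bsor) <- dimnames(jac)
mat_dt <- function(m) data.table::data.table(module = rownames(m),
                                             as.data.frame(m))
data.table::fwrite(mat_dt(jac), "results/taxon_jaccard.tsv", sep = "\t")
data.table::fwrite(mat_dt(bsor), "results/sorensen.tsv", sep = "\t")

br <- latitudinal_band_richness(agg, 10)
data.table::fwrite(br, "results/band_richness.tsv", sep = "\t")

boot1 <- resample_network(agg, seed = 101L)
p1 <- ml_cluster(boot1, cluster_params(num_trials = 10L, seed = 11L))
ov <- alluvial_overlap(list(part, p1))[[1]]
data.table::fwrite(ov, "results/alluvial_reference_vs_bootstrap.tsv", sep = "\t")
jsonlite::write_json(ov, "results/alluvial_reference_vs_bootstrap.json",
                     dataframe = "rows", auto_unbox = TRUE)
cat(sprintf("alluvial streamlines (reference vs one bootstrap): %d rows\n",
            nrow(ov)))
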