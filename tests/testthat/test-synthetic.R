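test_that("generator is reproducible and respects its contracts", {
  cfg <- synth_config(n_layers = 8L, boundaries = 4L, n_genera = 40L,
                      n_cells = 6L, seed = 77L)
  r1 <- generate_fossil_record(cfg)
  r2 <- generate_fossil_record(cfg)
  expect_identical(r1$occurrences, r2$occurrences)  # byte-identical

  # aggregated counts always satisfy 1 <= n <= N
  agg <- aggregate_occurrences(r1$occurrences)
  expect_true(all(agg$n_genus >= 1L & agg$n_genus <= agg$N_total))

  expect_error(synth_config(boundaries = c(5L, 3L)), "increasing")
  expect_error(synth_config(boundaries = 3L, styles = c("x")), "abrupt")
  expect_error(synth_config(taxon_sharing = 1), "taxon_sharing")
})

test_that("zero sharing with abrupt boundaries separates genus sets", {
  cfg <- synth_config(n_layers = 8L, boundaries = 4L, n_genera = 40L,
                      n_cells = 6L, taxon_sharing = 0, seed = 13L)
  rec <- generate_fossil_record(cfg)
  occ <- rec$occurrences
  early <- unique(occ[stage_index < 4L, genus])
  late <- unique(occ[stage_index >= 4L, genus])
  expect_equal(length(intersect(early, late)), 0L)
})

test_that("recovery score is exact on the truth and near zero on noise", {
  run <- default_pipeline()
  truth <- run$rec$truth
  sc <- recovery_score(truth, run$part)
  expect_equal(length(sc$boundary_offsets), nrow(truth$boundaries))

  # partition equal to the truth: AMI 1, offsets 0
  ideal <- data.table::copy(run$part)
  block <- findInterval(ideal$layer, c(0L, run$rec$config$boundaries))
  ideal[, top := block]
  ideal[, path := as.character(block)]
  sc1 <- recovery_score(truth, ideal)
  expect_equal(sc1$ami, 1)
  expect_true(all(sc1$boundary_offsets == 0L))

  # random halves: AMI ~ 0 on average
  set.seed(33)
  amis <- replicate(20, {
    noise <- data.table::copy(run$part)
    noise[, top := sample(1:2, .N, replace = TRUE)]
    recovery_score(truth, noise)$ami
  })
  expect_lt(abs(mean(amis)), 0.02)
})

test_that("taxon sharing raises the recovered inter-assemblage Jaccard", {
  # the two planted blocks are identified in the recovered partition by the
  # module carrying the most flow of each side's genera, so recovery noise
  # in the smaller modules cannot mask the sharing signal
  rep_jaccard <- function(rec, p) {
    tr <- rec$truth$genus_assemblage
    gmod <- data.table::as.data.table(p)[type == "genus",
                                         .(flow = sum(flow)), by = .(name, top)]
    gmod <- merge(gmod, tr, by.x = "name", by.y = "genus",
                  allow.cartesian = TRUE)
    reps <- gmod[, .(flow = sum(flow)), by = .(assemblage, top)][
      , .SD[which.max(flow)], by = assemblage]
    taxon_jaccard(p, reps$top[1], reps$top[2])
  }
  js <- vapply(c(0, 0.1, 0.25), function(sh) {
    cfg <- synth_config(n_layers = 20L, boundaries = 10L, n_genera = 200L,
                        n_cells = 20L, taxon_sharing = sh, seed = 55L)
    rec <- generate_fossil_record(cfg)
    net <- assemble_network(aggregate_occurrences(rec$occurrences))
    p <- ml_cluster(net, cluster_params(num_trials = 8L, seed = 5L))
    rep_jaccard(rec, p)
  }, 0)
  expect_true(all(diff(js) > 0))
  expect_lt(js[1], 0.02)
})

test_that("two-province mode plants recoverable lower-level structure", {
  cfg <- synth_config(n_layers = 6L, boundaries = 3L, n_genera = 60L,
                      n_cells = 12L, provinces = 2L, seed = 14L)
  rec <- generate_fossil_record(cfg)
  expect_s3_class(rec$occurrences, "occurrences")
  # truth file serializes
  f <- tempfile()
  write_truth(rec, f)
  tr <- data.table::fread(f)
  expect_true(all(c("genus", "assemblage") %in% names(tr)))
})
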