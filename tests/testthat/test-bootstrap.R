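test_that("truncated Poisson draws respect their support", {
  expect_equal(rtrunc_poisson(20, 1, 1), rep(1L, 20))
  set.seed(1)
  draws <- rtrunc_poisson(2000, 3, 10)
  expect_true(all(draws >= 1 & draws <= 10))
  expect_error(rtrunc_poisson(1, 0.5, 3), "mean")
  expect_error(rtrunc_poisson(1, 5, 3), "mean")
})

test_that("truncated Poisson mean matches the closed form", {
  set.seed(2)
  draws <- rtrunc_poisson(10000, 3, 10)
  m <- fossilflows:::trunc_poisson_mean(3, 10)
  pmf <- dpois(1:10, 3) / sum(dpois(1:10, 3))
  se <- sqrt(sum((1:10 - m)^2 * pmf) / 10000)
  expect_lt(abs(mean(draws) - m), 3 * se)
})

test_that("resampling preserves the link set and the weight contracts", {
  agg <- toy_agg()
  net <- assemble_network(agg)
  bnet <- resample_network(agg, seed = 9L)
  expect_equal(bnet$links[, .(layer, u, v)], net$links[, .(layer, u, v)])
  expect_true(all(bnet$links$w > 0 & bnet$links$w <= 1))
  # n = N = 1 always resamples to weight 1
  agg2 <- as_agg_counts(data.table::data.table(
    stage_index = 0L, cell_id = c("q0r0", "q1r0"), genus = "ga",
    n_genus = c(1L, 2L), N_total = c(1L, 4L)))
  for (s in 1:5)
    expect_equal(resample_network(agg2, s)$links[1, w], 1)
  # reproducible from seed
  expect_equal(resample_network(agg, 5L)$links$w,
               resample_network(agg, 5L)$links$w)
  # resampled mean for (n = 3, N = 10) matches the truncated mean / N
  agg3 <- as_agg_counts(data.table::data.table(
    stage_index = 0L, cell_id = sprintf("q%dr0", 1:10000),
    genus = "ga", n_genus = 3L, N_total = 10L))
  w <- resample_network(agg3, 7L)$links$w
  m <- fossilflows:::trunc_poisson_mean(3, 10) / 10
  pmf <- dpois(1:10, 3) / sum(dpois(1:10, 3))
  se <- sqrt(sum((1:10 / 10 - m)^2 * pmf) / 10000)
  expect_lt(abs(mean(w) - m), 3 * se)
})

test_that("best-match Jaccard picks the argmax with stated tie-breaks", {
  p <- data.table::data.table(state = 1:12,
                              top = c(rep(1L, 5), rep(2L, 7)))
  # A = {1..10}: J with {1..5} = 5/10, with {6..12} = 5/12
  bm <- best_match_jaccard(1:10, p)
  expect_equal(bm$module, 1L)
  expect_equal(bm$similarity, 0.5)
  full <- best_match_jaccard(6:12, p)
  expect_equal(full$module, 2L)
  expect_equal(full$similarity, 1)
  # disjoint reference matches nothing
  expect_equal(best_match_jaccard(13:20, p)$similarity, 0)
  # tie on similarity and size goes to the smaller module id
  ptie <- data.table::data.table(state = 1:4, top = c(1L, 1L, 2L, 2L))
  expect_equal(best_match_jaccard(c(2L, 3L), ptie)$module, 1L)
  expect_error(best_match_jaccard(integer(0), p), "empty")
})

test_that("module support and per-layer significance contracts hold", {
  run <- default_pipeline()
  ref <- run$part
  # identical ensemble: P05 = P07 = 1 and per-layer significance 1
  ens <- list(ref, ref, ref)
  sup <- module_support(ref, ens)
  expect_true(all(sup$P05 == 1 & sup$P07 == 1))
  sig <- per_layer_significance(ref, ens)
  expect_true(all(sig$median_probability == 1))

  # singleton-module ensemble: P05 = 0 for any module with > 3 nodes
  singletons <- data.table::copy(ref)[, top := state]
  sup0 <- module_support(ref, list(singletons))
  expect_true(all(sup0$P05 == 0))

  # P07 <= P05 on a genuinely resampled ensemble
  boot <- bootstrap_ensemble(run$agg,
                             params = cluster_params(num_trials = 3L),
                             replicates = 3L, seed = 31L)
  sup2 <- module_support(ref, boot)
  expect_true(all(sup2$P07 <= sup2$P05))
})

test_that("a layer split from its reference module in half the replicates scores 0.5", {
  run <- default_pipeline()
  ref <- run$part
  tampered <- data.table::copy(ref)
  lay0 <- tampered$layer == 0L
  tampered[lay0, top := max(ref$top) + 1L]
  sig <- per_layer_significance(ref, list(ref, tampered))
  expect_equal(sig[layer == 0L, median_probability], 0.5)
  expect_true(all(sig[layer > 0L, median_probability] == 1))
})

test_that("ensemble directories carry tree files and a manifest", {
  run <- default_pipeline()
  dir <- file.path(tempdir(), "boot_ens")
  boot <- bootstrap_ensemble(run$agg,
                             params = cluster_params(num_trials = 2L),
                             replicates = 2L, seed = 77L, dir = dir)
  expect_equal(length(list.files(dir, pattern = "\\.tree$")), 2L)
  manifest <- readLines(file.path(dir, "manifest.jsonl"))
  expect_equal(length(manifest), 2L)
  rec <- jsonlite::fromJSON(manifest[1])
  expect_true(all(c("replicate", "resample_seed", "codelength") %in% names(rec)))
})
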