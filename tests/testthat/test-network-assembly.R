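test_that("layer merging pools counts before weights are computed", {
  agg <- toy_agg()
  ident <- merge_layers(agg, c(0L, 1L))
  expect_equal(ident[, .(stage_index, cell_id, genus, n_genus, N_total)],
               agg[, .(stage_index, cell_id, genus, n_genus, N_total)])

  merged <- merge_layers(agg, c(0L, 0L))
  # (n=2,N=3) and (n=1,N=2) for ga/gb at q0r0 pool additively
  expect_equal(merged[cell_id == "q0r0" & genus == "ga", n_genus], 2L)
  expect_equal(merged[cell_id == "q0r0" & genus == "gb", n_genus], 2L)
  expect_equal(unique(merged[cell_id == "q0r0", N_total]), 5L)
  expect_equal(unique(merged$stage_index), 0L)

  expect_error(merge_layers(agg, c(1L, 0L)), "monotone")
  expect_error(merge_layers(agg, c(0L, 2L)), "surjective")
})

test_that("assembly creates the bipartite multilayer structure", {
  agg <- toy_agg()
  net <- assemble_network(agg)
  # one link per aggregated entry, weight n/N
  expect_equal(nrow(net$links), nrow(agg))
  w <- net$links[order(layer, u, v), w]
  expect_true(all(w > 0 & w <= 1))
  expect_equal(sort(net$links$w), sort(agg$n_genus / agg$N_total))
  # node bookkeeping identity
  expect_equal(nrow(net$phys),
               data.table::uniqueN(agg$genus) +
                 nrow(unique(agg[, .(stage_index, cell_id)])))
  # genus state per layer of occurrence; cells one state each
  expect_equal(nrow(net$states),
               nrow(unique(agg[, .(genus, stage_index)])) +
                 nrow(unique(agg[, .(stage_index, cell_id)])))
  # every link endpoint exists and weights hit 1 iff genus is in every
  # collection of the cell
  expect_true(all(c(net$links$u, net$links$v) <= nrow(net$states)))

  bad <- data.table::copy(agg)
  bad$n_genus[1] <- bad$N_total[1] + 1L
  expect_error(as_agg_counts(bad), "exceeds")
})

test_that("assembly is a pure function of the counts", {
  agg <- toy_agg()
  f1 <- tempfile(); f2 <- tempfile()
  write_multilayer_network(assemble_network(agg), f1)
  write_multilayer_network(assemble_network(data.table::copy(agg)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("merging the two terminal Cambrian stages drops the layer count by one", {
  ts <- read_timescale(system.file("extdata", "ics_stages.tsv",
                                   package = "fossilflows"))
  expect_equal(nrow(ts), 100L)
  mm <- merge_map_for_stages(ts, c("Jiangshanian", "Stage 10"))
  expect_equal(max(mm) + 1L, 99L)
  expect_equal(unname(mm[ts$stage == "Jiangshanian"]),
               unname(mm[ts$stage == "Stage 10"]))
})
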