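test_that("AMI identities and symmetry hold", {
  x <- c(1, 1, 2, 2, 3, 3)
  expect_equal(ami(x, x), 1)
  expect_equal(ami(x, rep(1, 6)), 0)
  expect_equal(ami(x, sample(c("a", "b", "c"))[x]), ami(sample(c("a","b","c"))[x], x))
  expect_error(ami(x, x[-1]), "length")
  # permutation invariance of labels
  y <- c(2, 2, 1, 1, 3, 3)
  expect_equal(ami(x, y), 1)
})

test_that("AMI matches an independently computed contingency-table value", {
  # frozen from scikit-learn's adjusted_mutual_info_score
  a <- c(1, 1, 1, 1, 2, 2, 2, 2)
  b <- c(1, 1, 2, 2, 1, 1, 2, 2)
  expect_equal(ami(a, b), -0.12974472642510582, tolerance = 1e-10)
  a2 <- c(1, 1, 2, 2, 3, 3)
  b2 <- c(1, 2, 1, 2, 3, 3)
  expect_equal(ami(a2, b2), 0.1666666666666672, tolerance = 1e-10)
})

test_that("taxon Jaccard works on genus sets with overlap allowed", {
  run <- default_pipeline()
  p <- run$part
  tops <- top_modules(p)
  expect_equal(taxon_jaccard(p, tops[1], tops[1]), 1)
  j <- taxon_jaccard(p, tops[1], tops[2])
  expect_gte(j, 0)
  expect_lt(j, 1)
  expect_error(taxon_jaccard(p, tops[1], 9999L), "unknown module")
  # direct arithmetic on constructed module genus sets
  toy <- data.table::data.table(
    state = 1:6, name = c("a", "b", "c", "b", "c", "d"),
    type = "genus", top = c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(taxon_jaccard(toy, 1L, 2L), 0.5)  # {a,b,c} vs {b,c,d}
})

test_that("Sorensen dissimilarity follows its formula", {
  expect_equal(sorensen_dissimilarity(c("a", "b"), c("a", "b")), 0)
  expect_equal(sorensen_dissimilarity(c("a"), c("b")), 1)
  expect_equal(sorensen_dissimilarity(c("x", "a"), c("x", "b")), 0.5)
  expect_error(sorensen_dissimilarity(character(0), character(0)), "non-empty")
})

test_that("Jaccard and Sorensen satisfy J = (1 - B) / (1 + B) on random sets", {
  set.seed(10)
  pool <- sprintf("g%03d", 1:60)
  for (i in 1:25) {
    A <- sample(pool, sample(5:40, 1))
    B <- sample(pool, sample(5:40, 1))
    bsor <- sorensen_dissimilarity(A, B)
    J <- length(intersect(A, B)) / length(union(A, B))
    expect_equal(J, (1 - bsor) / (1 + bsor), tolerance = 1e-12)
  }
})

test_that("alluvial overlap tables have partition marginals", {
  run <- default_pipeline()
  p <- run$part
  ov <- alluvial_overlap(list(p, p))[[1]]
  expect_true(all(ov$module_a == ov$module_b))  # identical partitions: diagonal
  expect_equal(ov[, sum(shared), by = module_a][order(module_a), V1],
               p[, .N, by = top][order(top), N])

  moved <- data.table::copy(p)
  victim <- moved$state[1]
  other <- setdiff(unique(moved$top), moved$top[moved$state == victim])[1]
  moved[state == victim, top := other]
  ov2 <- alluvial_overlap(list(p, moved))[[1]]
  off <- ov2[module_a != module_b]
  expect_equal(nrow(off), 1L)
  expect_equal(off$shared, 1L)

  bad <- data.table::copy(p)[-1]
  expect_error(alluvial_overlap(list(p, bad)), "different state-node sets")
})

test_that("dominance timeline detects planted transitions", {
  run <- default_pipeline()
  tl <- dominance_timeline(run$part)
  shares <- tl$shares[, sum(share), by = layer]
  expect_equal(shares$V1, rep(1, nrow(shares)), tolerance = 1e-9)

  # single-module partition: share 1 everywhere, no transitions
  single <- data.table::copy(run$part)[, top := 1L]
  tl1 <- dominance_timeline(single)
  expect_equal(nrow(tl1$transitions), 0L)
  expect_true(all(tl1$shares$share == 1))

  # planted abrupt boundaries: the first shift happens after layer 9,
  # between layers 9 and 10, and is classified abrupt
  tl2 <- dominance_timeline(run$part)
  planted <- run$rec$config$boundaries
  expect_equal(nrow(tl2$transitions), length(planted))
  expect_equal(tl2$transitions$at_layer, planted)
  expect_equal(tl2$transitions$after_layer[1], 9L)
  expect_equal(tl2$transitions$at_layer[1], 10L)
  expect_true(all(tl2$transitions$style == "abrupt"))
})

test_that("timescale labels map layers through a merge", {
  ts <- read_timescale(system.file("extdata", "ics_stages.tsv",
                                   package = "fossilflows"))
  mm <- merge_map_for_stages(ts, c("Jiangshanian", "Stage 10"))
  fake <- data.table::data.table(state = 1:3, layer = c(0L, 8L, 98L))
  labs <- layer_labels(fake, ts, mm, "period")
  expect_equal(labs, c("Cambrian", "Cambrian", "Quaternary"))
  # merged layer takes the older constituent's label
  expect_equal(layer_labels(data.table::data.table(state = 1, layer = 8L),
                            ts, mm, "era"), "Paleozoic")
})
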