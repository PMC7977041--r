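test_that("hex assignment follows the declared tessellation", {
  grid <- hex_grid()
  origin_cell <- hex_cell_of(0, 0, grid)
  expect_equal(hex_cell_center(origin_cell, grid)$center_lat, 0)
  expect_equal(hex_cell_center(origin_cell, grid)$center_lon, 0)
  # points within half the inner diameter along a grid axis share the cell
  expect_equal(hex_cell_of(0, 0.1, grid), origin_cell)
  expect_equal(hex_cell_of(4.9, 0, grid), origin_cell)
  expect_error(hex_cell_of(95, 0, grid), "latitude")
  expect_error(hex_cell_of(0, 200, grid), "longitude")
})

test_that("assignment agrees with brute-force nearest-centre search", {
  grid <- hex_grid()
  # enumerate all canonical cell centres near the test points
  qs <- -24:24; rs <- -30:30
  centres <- data.table::CJ(q = qs, r = rs)
  xy <- hex_axial_to_xy(centres$q, centres$r, grid)
  centres[, `:=`(lon = xy$x, lat = xy$y)]
  centres <- centres[lon >= -180 & lon < 180 & abs(lat) <= 92]
  centres[, id := sprintf("q%dr%d", q, r)]

  set.seed(99)
  pts <- data.table::data.table(lat = stats::runif(200, -80, 80),
                                lon = stats::runif(200, -180, 179.99))
  got <- hex_cell_of(pts$lat, pts$lon, grid)
  for (i in seq_len(nrow(pts))) {
    dlon <- ((pts$lon[i] - centres$lon + 180) %% 360) - 180
    d <- dlon^2 + (pts$lat[i] - centres$lat)^2
    best <- centres$id[order(d, centres$id)][1]
    expect_equal(got[i], best)
  }
  # two points 10 degrees apart along the grid's east axis fall in
  # distinct adjacent cells
  c1 <- hex_cell_of(0, 0, grid)
  c2 <- hex_cell_of(0, 10, grid)
  expect_false(c1 == c2)
  ax1 <- fossilflows:::hex_cell_axial(c1)
  ax2 <- fossilflows:::hex_cell_axial(c2)
  expect_lte(abs(ax1$q - ax2$q) + abs(ax1$r - ax2$r), 2L)
})

toy_occ <- function() {
  ts <- as_timescale(data.table::data.table(
    stage = "A", period = "P", era = "E", age_base = 500, age_top = 490))
  as_occurrences(data.table::data.table(
    collection_id = c("c1", "c2", "c3", "c1", "c2", "c2"),
    genus = c("gA", "gA", "gB", "gB", "gB", "gC"),
    paleolat = 0.5, paleolon = 0.5, stage = "A"), ts)
}

test_that("aggregation counts distinct collections per cell and genus", {
  agg <- aggregate_occurrences(toy_occ())
  expect_equal(unique(agg$N_total), 3L)  # three distinct collections
  expect_equal(agg[genus == "gA", n_genus], 2L)
  expect_equal(agg[genus == "gB", n_genus], 3L)
  expect_equal(agg[genus == "gC", n_genus], 1L)
  expect_true(all(agg$n_genus >= 1L & agg$n_genus <= agg$N_total))
})

test_that("binning is permutation-invariant and origin changes only ids", {
  rec <- generate_fossil_record(synth_config(n_layers = 4L, boundaries = 2L,
                                             n_genera = 40L, n_cells = 8L,
                                             seed = 3L))
  occ <- rec$occurrences
  agg1 <- aggregate_occurrences(occ)
  agg2 <- aggregate_occurrences(occ[sample(nrow(occ))])
  expect_equal(agg1, agg2, ignore_attr = TRUE)

  shifted <- aggregate_occurrences(occ, hex_grid(origin_lon = 2))
  expect_equal(sum(shifted$n_genus), sum(agg1$n_genus))
  unique_colls <- function(a) sum(unique(a[, .(stage_index, cell_id, N_total)])$N_total)
  expect_equal(unique_colls(shifted), unique_colls(agg1))
})

test_that("latitudinal band richness counts distinct genera per band", {
  agg <- aggregate_occurrences(toy_occ())
  br <- latitudinal_band_richness(agg, 10)
  expect_equal(br[band_lower == 0, richness], 3L)
  expect_error(latitudinal_band_richness(agg, -1), "band_width")

  # uniform occupancy: per-band richness close to a direct recount
  rec <- generate_fossil_record(synth_config(n_layers = 3L, boundaries = 1L,
                                             n_genera = 60L, n_cells = 12L,
                                             seed = 8L))
  agg2 <- aggregate_occurrences(rec$occurrences)
  br2 <- latitudinal_band_richness(agg2, 10)
  cells <- attr(agg2, "cells")
  direct <- merge(agg2, cells, by = "cell_id")
  direct[, band_lower := 10 * floor(center_lat / 10)]
  recount <- direct[, .(richness = data.table::uniqueN(genus)),
                    by = .(stage_index, band_lower)]
  expect_equal(br2[order(stage_index, band_lower), richness],
               recount[order(stage_index, band_lower), richness])
})
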