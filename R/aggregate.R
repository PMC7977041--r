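#' Aggregate occurrences onto the hexagonal grid, per stage
#'
#' For every (stage, cell) the total number of distinct collections
#' (`N_total`) and, for every genus recorded there, the number of distinct
#' collections registering it (`n_genus`) are counted. Entries with zero
#' count are never materialized, so the rows are exactly the occupied
#' (stage, cell, genus) triples and `1 <= n_genus <= N_total` holds
#' throughout. These counts are the numerator and denominator of the
#' cell-to-genus link weights.
#'
#' @param occ validated [as_occurrences()] table.
#' @param grid a [hex_grid()]; default 10-degree flat-top grid.
#' @return `data.table` of class `agg_counts` with columns `stage_index`,
#'   `cell_id`, `genus`, `n_genus`, `N_total`; the occupied-cell centres are
#'   attached as attribute `cells` and the grid as attribute `grid`.
#' @export
aggregate_occurrences <- function(occ, grid = hex_grid()) {
  stopifnot(inherits(occ, "occurrences"))
  if (nrow(occ) == 0L) {
    out <- data.table::data.table(stage_index = integer(), cell_id = character(),
                                  genus = character(), n_genus = integer(),
                                  N_total = integer())
    return(finish_agg(out, grid))
  }
  dt <- data.table::copy(occ)
  dt[, cell_id := hex_cell_of(paleolat, paleolon, grid)]
  totals <- dt[, .(N_total = data.table::uniqueN(collection_id)),
               by = .(stage_index, cell_id)]
  counts <- dt[, .(n_genus = data.table::uniqueN(collection_id)),
               by = .(stage_index, cell_id, genus)]
  out <- totals[counts, on = c("stage_index", "cell_id")]
  data.table::setcolorder(out, c("stage_index", "cell_id", "genus", "n_genus", "N_total"))
  data.table::setorder(out, stage_index, cell_id, genus)
  finish_agg(out, grid)
}

finish_agg <- function(out, grid) {
  cells <- hex_cell_center(unique(out$cell_id), grid)
  data.table::setattr(out, "cells", cells)
  data.table::setattr(out, "grid", grid)
  data.table::setattr(out, "class", c("agg_counts", class(data.table::data.table())))
  out[]
}

#' Coerce a plain table of counts into aggregated-counts form
#'
#' For replaying externally aggregated data (e.g. a published supplementary
#' table) through the network assembly. Validates the count invariants.
#'
#' @param dt data.frame with columns `stage_index`, `cell_id`, `genus`,
#'   `n_genus`, `N_total`.
#' @param grid grid used to derive cell centres from the ids (needed only by
#'   [latitudinal_band_richness()]).
#' @export
as_agg_counts <- function(dt, grid = hex_grid()) {
  dt <- data.table::as.data.table(dt)
  require_columns(dt, c("stage_index", "cell_id", "genus", "n_genus", "N_total"),
                  "aggregated counts")
  if (any(dt$n_genus < 1L))
    stop("aggregated counts: n_genus must be >= 1 (zero-count entries are omitted)")
  if (any(dt$n_genus > dt$N_total))
    stop("aggregated counts: n_genus exceeds N_total at row(s) ",
         paste(head(which(dt$n_genus > dt$N_total), 5L), collapse = ", "))
  incons <- dt[, data.table::uniqueN(N_total), by = .(stage_index, cell_id)]
  if (any(incons$V1 != 1L))
    stop("aggregated counts: N_total must be constant within a (stage, cell)")
  finish_agg(dt, grid)
}

#' Write / read aggregated counts as a 5-column delimited table
#' @param agg aggregated counts.
#' @param path output file.
#' @export
write_agg_counts <- function(agg, path) {
  data.table::fwrite(agg[, .(stage_index, cell_id, genus, n_genus, N_total)],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_agg_counts
#' @param grid grid spec used to recompute cell centres.
#' @export
read_agg_counts <- function(path, grid = hex_grid()) {
  dt <- data.table::fread(path, sep = "\t", showProgress = FALSE,
                          colClasses = list(character = c("cell_id", "genus")))
  as_agg_counts(dt, grid)
}

#' Genus richness in latitudinal bands per stage
#'
#' Counts, for every stage and latitudinal band `[b, b + band_width)` starting
#' at -90, the number of distinct genera whose occupied cells have centres in
#' the band. Raw counts only; a genus spanning several bands is counted in
#' each.
#'
#' @param agg aggregated counts.
#' @param band_width band width in degrees (default 10).
#' @return data.table with `stage_index`, `band_lower`, `richness`.
#' @export
latitudinal_band_richness <- function(agg, band_width = 10) {
  stopifnot(inherits(agg, "agg_counts"))
  if (band_width <= 0) stop("band_width must be > 0")
  cells <- attr(agg, "cells")
  dt <- merge(agg, cells, by = "cell_id")
  dt[, band_lower := band_width * floor(center_lat / band_width)]
  out <- dt[, .(richness = data.table::uniqueN(genus)),
            by = .(stage_index, band_lower)]
  data.table::setorder(out, stage_index, band_lower)
  out[]
}
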