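#' Configuration for the synthetic fossil record generator
#'
#' Defines a planted mega-assemblage structure: `n_assemblages =
#' length(boundaries) + 1` global taxon pools that successively dominate the
#' record, with dominance shifting at the boundary layers either abruptly
#' (one-layer switch) or protractedly (cell-level residency mixing the two
#' pools with linearly shifting weights over `ramp_length` layers). Genus
#' ranges are contiguous layer intervals drawn uniformly within their
#' assemblage's span; a `taxon_sharing` fraction of each pool is shared with
#' the temporally adjacent pool (those genera range across the boundary).
#' Sampling emulates collection-based fossil data: each (layer, cell) holds
#' `Poisson(collections_per_cell)` collections (at least 1), a resident genus
#' enters a cell with probability `cell_occupancy` and is then recorded in
#' `Binomial(collections, occupancy)` of its collections.
#'
#' The defaults plant four assemblages over 40 layers with abrupt boundaries
#' at layers 10, 25 and 33, 300 genera per assemblage, 5% sharing, 30 cells
#' per layer and genera occupying ~10% of cells (clean planted structure for
#' recovery benchmarks); protracted shifts are exercised by passing
#' `styles = c(..., "protracted")`, which emulates a gradual dominance
#' turnover like the mid-Cretaceous one.
#'
#' @param n_layers number of stages/layers.
#' @param boundaries strictly increasing layer indices in `(0, n_layers)`
#'   where dominance shifts (the first layer dominated by the new
#'   assemblage).
#' @param styles per-boundary `"abrupt"` or `"protracted"`.
#' @param ramp_length ramp width (layers) of protracted shifts.
#' @param n_genera genera per assemblage.
#' @param taxon_sharing fraction of genera shared between adjacent
#'   assemblages, in `[0, 1)`.
#' @param n_cells grid cells per layer.
#' @param collections_per_cell Poisson mean of collections per (layer, cell).
#' @param cell_occupancy probability a resident genus enters a given cell.
#' @param occupancy per-collection recording probability within an entered
#'   cell.
#' @param range_coverage minimum genus range length as a fraction of the
#'   assemblage span (range lengths are uniform on
#'   `[range_coverage * span, span]`).
#' @param provinces 1 (exchangeable cells) or 2 (two geographic provinces
#'   with partially province-restricted pools, planting lower-level
#'   bioregions).
#' @param seed integer seed; the generator is a pure function of the config.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_layers = 40L, boundaries = c(10L, 25L, 33L),
                         styles = rep("abrupt", length(boundaries)),
                         ramp_length = 4L, n_genera = 300L,
                         taxon_sharing = 0.05, n_cells = 30L,
                         collections_per_cell = 12, cell_occupancy = 0.1,
                         occupancy = 0.3, range_coverage = 0.75,
                         provinces = 1L, seed = 42L) {
  if (range_coverage <= 0 || range_coverage > 1)
    stop("range_coverage must be in (0, 1]")
  boundaries <- as.integer(boundaries)
  if (length(boundaries) > 0L &&
      (any(diff(boundaries) <= 0L) || any(boundaries <= 0L) ||
       any(boundaries >= n_layers)))
    stop("boundaries must be strictly increasing within (0, n_layers)")
  if (length(styles) != length(boundaries))
    stop("need one style per boundary")
  if (!all(styles %in% c("abrupt", "protracted")))
    stop("styles must be 'abrupt' or 'protracted'")
  if (taxon_sharing < 0 || taxon_sharing >= 1) stop("taxon_sharing must be in [0, 1)")
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must be in (0, 1]")
  if (cell_occupancy <= 0 || cell_occupancy > 1) stop("cell_occupancy must be in (0, 1]")
  if (!provinces %in% c(1L, 2L)) stop("provinces must be 1 or 2")
  structure(list(n_layers = as.integer(n_layers), boundaries = boundaries,
                 styles = styles, ramp_length = as.integer(ramp_length),
                 n_genera = as.integer(n_genera), taxon_sharing = taxon_sharing,
                 n_cells = as.integer(n_cells),
                 collections_per_cell = collections_per_cell,
                 cell_occupancy = cell_occupancy, occupancy = occupancy,
                 range_coverage = range_coverage,
                 provinces = as.integer(provinces), seed = as.integer(seed)),
            class = "synth_config")
}

#' Timescale for a synthetic record
#'
#' Stages `S01..Snn`, 5 Ma each, oldest at 500 Ma; periods are 5-stage
#' blocks, eras follow the planted dominance spans (so era labels are the
#' planted assemblages' reigns).
#'
#' @param config `synth_config`.
#' @export
synthetic_timescale <- function(config) {
  t <- config$n_layers
  span_start <- c(0L, config$boundaries)
  era_of <- findInterval(0:(t - 1L), span_start)
  as_timescale(data.table::data.table(
    stage = sprintf("S%02d", 1:t),
    period = sprintf("P%d", (0:(t - 1L)) %/% 5L + 1L),
    era = sprintf("E%d", era_of),
    age_base = 500 - 5 * (0:(t - 1L)),
    age_top = 500 - 5 * (1:t)))
}

# mixture weight of the *incoming* assemblage at layer l for boundary b
ramp_weight <- function(l, b, style, ramp) {
  if (style == "abrupt") return(as.numeric(l >= b))
  pmin(1, pmax(0, 0.5 + (l - b + 0.5) / ramp))
}

# per-layer assemblage mixture weights (rows = layers, cols = assemblages)
assemblage_weights <- function(config) {
  t <- config$n_layers
  A <- length(config$boundaries) + 1L
  W <- matrix(0, nrow = t, ncol = A)
  W[, 1L] <- 1
  for (k in seq_along(config$boundaries)) {
    wk <- ramp_weight(0:(t - 1L), config$boundaries[k], config$styles[k],
                      config$ramp_length)
    # weight wk moves from the union of assemblages 1..k to assemblage k+1
    W[, seq_len(k)] <- W[, seq_len(k), drop = FALSE] * (1 - wk)
    W[, k + 1L] <- wk
  }
  W
}

#' Generate a synthetic fossil occurrence record with planted assemblages
#'
#' @param config a [synth_config()].
#' @return list of class `synth_record`: `occurrences` (validated occurrence
#'   table), `timescale`, `truth` (genus labels, per-layer dominant
#'   assemblage, boundaries) and `config`.
#' @export
generate_fossil_record <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  t <- config$n_layers
  A <- length(config$boundaries) + 1L
  ts <- synthetic_timescale(config)
  grid <- hex_grid()

  # dominance spans (first..last dominated layer) and activity spans
  # (extended by half a ramp on protracted sides)
  span_lo <- c(0L, config$boundaries)
  span_hi <- c(config$boundaries - 1L, t - 1L)
  act_lo <- span_lo; act_hi <- span_hi
  for (k in seq_along(config$boundaries)) {
    if (config$styles[k] == "protracted") {
      ext <- ceiling(config$ramp_length / 2)
      act_lo[k + 1L] <- max(0L, span_lo[k + 1L] - ext)
      act_hi[k] <- min(t - 1L, span_hi[k] + ext)
    }
  }

  res <- with_seed(config$seed, {
    # genus pools; shared genera belong to two adjacent assemblages
    n_shared <- round(config$taxon_sharing * config$n_genera)
    pool <- vector("list", A)
    labels <- list()
    next_id <- 1L
    for (a in seq_len(A)) {
      n_new <- config$n_genera - if (a > 1L) n_shared else 0L
      new_g <- sprintf("g%05d", next_id:(next_id + n_new - 1L))
      next_id <- next_id + n_new
      shared_g <- if (a > 1L && n_shared > 0L)
        sample(setdiff(pool[[a - 1L]], if (a > 2L) pool[[a - 2L]] else character(0)),
               n_shared) else character(0)
      pool[[a]] <- c(shared_g, new_g)
      labels[[a]] <- data.table::data.table(genus = pool[[a]], assemblage = a)
    }
    genus_labels <- data.table::rbindlist(labels)

    # contiguous ranges: unshared genera range within their assemblage's
    # activity span; shared genera range from the older span into the younger
    n_multi <- genus_labels[, .N, by = genus]
    range_of <- new.env(parent = emptyenv())
    for (a in seq_len(A)) {
      for (g in pool[[a]]) {
        if (n_multi[genus == g, N] == 2L && a > 1L && g %in% pool[[a - 1L]]) {
          # boundary-crossing survivors straddle the boundary narrowly
          # (1-3 layers each side), like holdover taxa
          b <- span_lo[a]
          lo <- max(act_lo[a - 1L], b - sample.int(3L, 1L))
          hi <- min(act_hi[a], b - 1L + sample.int(3L, 1L))
          assign(g, c(lo, hi), envir = range_of)
        } else if (!exists(g, envir = range_of)) {
          # contiguous range: length uniform on [range_coverage * span, span]
          # (high coverage keeps assemblages internally cohesive), start
          # uniform among feasible positions
          span <- act_hi[a] - act_lo[a] + 1L
          lmin <- max(1L, ceiling(config$range_coverage * span))
          len <- if (lmin >= span) span else sample(lmin:span, 1L)
          start <- act_lo[a] + sample.int(span - len + 1L, 1L) - 1L
          assign(g, c(start, start + len - 1L), envir = range_of)
        }
      }
    }

    # province structure (optional two-province mode)
    prov_of_genus <- stats::setNames(rep(0L, next_id - 1L),
                                     sprintf("g%05d", seq_len(next_id - 1L)))
    if (config$provinces == 2L) {
      for (a in seq_len(A)) {
        gs <- pool[[a]]
        k <- sample(rep_len(0:2, length(gs)))  # 0 cosmopolitan, 1/2 province
        prov_of_genus[gs] <- k
      }
    }

    # fixed set of grid cells (hex centres, |lat| <= 60), reused every layer
    cells <- synthetic_cells(config$n_cells, grid)
    prov_of_cell <- rep_len(1:2, nrow(cells))

    W <- assemblage_weights(config)
    rows <- vector("list", t * config$n_cells)
    ri <- 0L
    for (l in 0:(t - 1L)) {
      w_l <- W[l + 1L, ]
      active <- which(w_l > 0)
      # residents per active assemblage at this layer
      res_by_a <- lapply(active, function(a) {
        gs <- pool[[a]]
        keep <- vapply(gs, function(g) {
          rg <- get(g, envir = range_of)
          l >= rg[1L] && l <= rg[2L]
        }, TRUE)
        gs[keep]
      })
      for (ci in seq_len(config$n_cells)) {
        a_cell <- if (length(active) == 1L) active else
          active[sample.int(length(active), 1L, prob = w_l[active])]
        residents <- res_by_a[[match(a_cell, active)]]
        if (config$provinces == 2L) {
          pv <- prov_of_genus[residents]
          residents <- residents[pv == 0L | pv == prov_of_cell[ci]]
        }
        if (length(residents) == 0L) next
        N <- max(1L, stats::rpois(1L, config$collections_per_cell))
        entered <- residents[stats::runif(length(residents)) < config$cell_occupancy]
        if (length(entered) == 0L) next
        counts <- stats::rbinom(length(entered), N, config$occupancy)
        entered <- entered[counts > 0L]
        counts <- counts[counts > 0L]
        if (length(entered) == 0L) next
        coll <- unlist(lapply(counts, function(cnt) sample.int(N, cnt)),
                       use.names = FALSE)
        occ <- data.table::data.table(
          collection_id = sprintf("L%02dC%02dK%02d", l, ci, coll),
          genus = rep(entered, counts),
          paleolat = cells$center_lat[ci],
          paleolon = cells$center_lon[ci],
          stage = ts$stage[l + 1L])
        ri <- ri + 1L
        rows[[ri]] <- occ
      }
    }
    list(occ = data.table::rbindlist(rows[seq_len(ri)]),
         genus_labels = genus_labels)
  })

  dominant <- max.col(assemblage_weights(config), ties.method = "last")
  truth <- list(
    genus_assemblage = res$genus_labels,
    layer_dominant = data.table::data.table(layer = 0:(t - 1L),
                                            assemblage = dominant),
    boundaries = data.table::data.table(layer = config$boundaries,
                                        style = config$styles,
                                        ramp_length = ifelse(
                                          config$styles == "protracted",
                                          config$ramp_length, 1L)))
  structure(list(occurrences = as_occurrences(res$occ, ts),
                 timescale = ts, truth = truth, config = config),
            class = "synth_record")
}

# deterministic pick of n hexagonal cells with centre |lat| <= 60
synthetic_cells <- function(n, grid) {
  qs <- -15:15
  out <- list()
  for (r in -8:8) {
    for (q in qs) {
      xy <- hex_axial_to_xy(q, r, grid)
      lat <- grid$origin_lat + xy$y
      lon <- grid$origin_lon + xy$x
      if (abs(lat) <= 60 && lon >= -180 && lon < 180)
        out[[length(out) + 1L]] <- data.table::data.table(
          q = q, r = r, center_lat = lat, center_lon = lon)
    }
  }
  cells <- data.table::rbindlist(out)
  data.table::setorder(cells, r, q)
  if (nrow(cells) < n) stop("grid too coarse for the requested number of cells")
  # spread picks evenly through the ordered list
  cells[round(seq(1, nrow(cells), length.out = n))]
}

#' Write the planted truth to a delimited file
#' @param record a `synth_record`.
#' @param path output file.
#' @export
write_truth <- function(record, path) {
  dt <- data.table::copy(record$truth$genus_assemblage)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Score the recovery of planted structure by a partition
#'
#' Adjusted mutual information between planted assemblage labels and
#' recovered top-module labels over unshared genera (shared genera are
#' excluded: their planted truth is multi-label). A genus's recovered label
#' is the top module carrying the most of its state-node flow. Also reports,
#' for each planted boundary, the signed layer offset to the nearest detected
#' dominance transition.
#'
#' @param truth `truth` element of a [generate_fossil_record()] result.
#' @param p `ml_partition` obtained by clustering the generated record.
#' @return list with `ami`, `boundary_offsets` (one per planted boundary,
#'   `NA` if no transition was detected), `timeline` (the
#'   [dominance_timeline()]), and `n_major_modules`.
#' @export
recovery_score <- function(truth, p) {
  multi <- truth$genus_assemblage[, .N, by = genus][N > 1L, genus]
  planted <- truth$genus_assemblage[!genus %in% multi]
  gmod <- p[type == "genus", .(flow = sum(flow)), by = .(name, top)]
  gmod <- gmod[, .SD[which.max(flow)], by = name]
  merged <- merge(planted, gmod, by.x = "genus", by.y = "name")
  score <- ami(merged$assemblage, merged$top)

  tl <- dominance_timeline(p)
  detected <- tl$transitions$at_layer
  offsets <- vapply(truth$boundaries$layer, function(b) {
    if (length(detected) == 0L) return(NA_integer_)
    as.integer(detected[which.min(abs(detected - b))] - b)
  }, NA_integer_)
  list(ami = score, boundary_offsets = offsets, timeline = tl,
       n_major_modules = length(top_modules(p)))
}
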