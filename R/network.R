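#' Pool stages into layers
#'
#' Re-indexes aggregated counts through a stage-to-layer merge map, pooling
#' the genus counts (`n_genus`) and collection totals (`N_total`) of merged
#' stages per cell BEFORE link weights are computed, so a weight of a merged
#' layer is (pooled n) / (pooled N), not an average of per-stage weights.
#'
#' @param agg aggregated counts keyed by `stage_index`.
#' @param merge_map integer vector mapping each stage_index (0-based position
#'   `stage_index + 1` in the vector) to a layer id; must be monotone
#'   non-decreasing and surjective onto `0..t-1` (see
#'   [merge_map_for_stages()]).
#' @return aggregated counts keyed by the merged layer ids.
#' @export
merge_layers <- function(agg, merge_map) {
  stopifnot(inherits(agg, "agg_counts"))
  merge_map <- as.integer(merge_map)
  if (any(diff(merge_map) < 0L))
    stop("merge_map must be monotone non-decreasing (layers keep temporal order)")
  layers <- sort(unique(merge_map))
  if (!identical(layers, 0:(length(layers) - 1L)))
    stop("merge_map must be surjective onto 0..t-1")
  if (nrow(agg) > 0L && max(agg$stage_index) + 1L > length(merge_map))
    stop("merge_map shorter than the number of stages present")

  dt <- data.table::copy(agg)
  dt[, layer := merge_map[stage_index + 1L]]
  totals <- unique(dt[, .(stage_index, cell_id, layer, N_total)])
  totals <- totals[, .(N_total = sum(N_total)), by = .(layer, cell_id)]
  counts <- dt[, .(n_genus = sum(n_genus)), by = .(layer, cell_id, genus)]
  out <- totals[counts, on = c("layer", "cell_id")]
  data.table::setnames(out, "layer", "stage_index")
  data.table::setcolorder(out, c("stage_index", "cell_id", "genus", "n_genus", "N_total"))
  data.table::setorder(out, stage_index, cell_id, genus)
  finish_agg(out, attr(agg, "grid"))
}

#' Assemble the bipartite multilayer network
#'
#' Builds the weighted bipartite multilayer network from aggregated counts:
#' layers are stages (post-merge), physical nodes are genera plus
#' spatiotemporal cells (one per occupied (cell, stage)), and each count
#' entry becomes one undirected intralayer link with weight
#' `w = n_genus / N_total` in (0, 1]. Genera get one state node per layer
#' where they have at least one link; each spatiotemporal cell is a
#' single-layer physical node with exactly one state. No interlayer links are
#' materialized: temporal coupling is dynamic, through the relax rate of the
#' random walker.
#'
#' @param agg aggregated (and optionally layer-merged) counts.
#' @return an object of class `ml_network` with elements `phys`
#'   (physical-node table), `states` (state-node table), `links`
#'   (state-to-state weighted links) and `n_layers`.
#' @export
assemble_network <- function(agg) {
  stopifnot(inherits(agg, "agg_counts"))
  if (nrow(agg) == 0L) stop("cannot assemble a network from empty counts")
  if (any(agg$n_genus > agg$N_total)) stop("entry with n_genus > N_total")
  layers_present <- sort(unique(agg$stage_index))
  # layer ids must be contiguous 0..t-1; re-index if some stages are empty
  lmap <- stats::setNames(seq_along(layers_present) - 1L, layers_present)

  dt <- agg[, .(layer = lmap[as.character(stage_index)], cell_id, genus,
                w = n_genus / N_total, n = n_genus, N = N_total)]

  genera <- sort(unique(dt$genus))
  cells <- unique(dt[, .(layer, cell_id)])
  data.table::setorder(cells, layer, cell_id)
  cells[, name := sprintf("%s@%d", cell_id, layer)]

  phys <- data.table::data.table(
    name = c(genera, cells$name),
    type = c(rep("genus", length(genera)), rep("cell", nrow(cells))))
  phys[, phys := .I]

  genus_states <- unique(dt[, .(genus, layer)])
  data.table::setorder(genus_states, genus, layer)
  states <- data.table::data.table(
    name = c(genus_states$genus, cells$name),
    layer = c(genus_states$layer, cells$layer),
    type = c(rep("genus", nrow(genus_states)), rep("cell", nrow(cells))))
  states[, phys := phys$phys[match(name, phys$name)]]
  data.table::setorder(states, phys, layer)
  states[, state := .I]

  skey <- stats::setNames(states$state, paste(states$name, states$layer))
  links <- data.table::data.table(
    layer = dt$layer,
    u = skey[paste(sprintf("%s@%d", dt$cell_id, dt$layer), dt$layer)],
    v = skey[paste(dt$genus, dt$layer)],
    w = dt$w, n = dt$n, N = dt$N)
  data.table::setorder(links, layer, u, v)

  new_ml_network(phys, states, links)
}

new_ml_network <- function(phys, states, links) {
  states[, `:=`(layer = as.integer(unname(layer)), phys = as.integer(unname(phys)))]
  links[, `:=`(layer = as.integer(unname(layer)), u = as.integer(unname(u)),
               v = as.integer(unname(v)))]
  n_layers <- max(states$layer) + 1L
  if (!identical(as.integer(sort(unique(states$layer))), 0:(n_layers - 1L)))
    stop("layer ids must form a contiguous 0..t-1 sequence")
  if (any(links$w <= 0) || any(links$w > 1 + 1e-12))
    stop("link weights must lie in (0, 1]")
  deg <- tabulate(c(links$u, links$v), nbins = nrow(states))
  if (any(deg == 0L)) stop("dangling state node(s) without intralayer links")
  structure(list(phys = phys, states = states, links = links,
                 n_layers = n_layers),
            class = "ml_network")
}

#' @export
print.ml_network <- function(x, ...) {
  cat(sprintf("multilayer network: %d physical nodes (%d genera + %d cells), %d state nodes, %d links, %d layers\n",
              nrow(x$phys), sum(x$phys$type == "genus"), sum(x$phys$type == "cell"),
              nrow(x$states), nrow(x$links), x$n_layers))
  invisible(x)
}

#' Write / read a multilayer network in link-list text form
#'
#' The format has a `*Vertices` section (`id "name"` per physical node) and
#' an `*Intra` section (`layer_id node_id node_id weight` per intralayer
#' link, physical ids). Weights are written with 15 significant digits so a
#' read/write round trip is stable to better than 1e-12. On reading, state
#' nodes are reconstructed (one per physical node and layer with links);
#' physical nodes whose name matches `<cell_id>@<layer>` are classified as
#' spatiotemporal cells.
#'
#' @param net `ml_network`.
#' @param path file path.
#' @export
write_multilayer_network <- function(net, path) {
  stopifnot(inherits(net, "ml_network"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("*Vertices", con)
  writeLines(sprintf("%d \"%s\"", net$phys$phys, net$phys$name), con)
  writeLines("*Intra", con)
  up <- net$states$phys[net$links$u]
  vp <- net$states$phys[net$links$v]
  writeLines(sprintf("%d %d %d %.15g", net$links$layer, up, vp, net$links$w), con)
  invisible(path)
}

#' @rdname write_multilayer_network
#' @export
read_multilayer_network <- function(path) {
  lines <- readLines(path)
  iv <- which(lines == "*Vertices")
  ii <- which(lines == "*Intra")
  if (length(iv) != 1L || length(ii) != 1L || ii < iv)
    stop("malformed multilayer file: need one *Vertices then one *Intra section")
  vlines <- lines[(iv + 1L):(ii - 1L)]
  m <- regmatches(vlines, regexec("^([0-9]+) \"(.*)\"$", vlines))
  if (any(lengths(m) != 3L)) stop("malformed *Vertices line(s)")
  phys <- data.table::data.table(
    phys = as.integer(vapply(m, `[`, "", 2L)),
    name = vapply(m, `[`, "", 3L))
  data.table::setorder(phys, phys)
  if (!identical(phys$phys, seq_len(nrow(phys))))
    stop("*Vertices ids must be 1..n")
  phys[, type := ifelse(grepl("@[0-9]+$", name), "cell", "genus")]
  data.table::setcolorder(phys, c("name", "type", "phys"))

  ilines <- lines[(ii + 1L):length(lines)]
  ilines <- ilines[nzchar(ilines)]
  parts <- data.table::fread(text = ilines, sep = " ", header = FALSE,
                             col.names = c("layer", "pu", "pv", "w"))
  if (any(parts$pu > nrow(phys)) || any(parts$pv > nrow(phys)) ||
      any(parts$pu < 1L) || any(parts$pv < 1L))
    stop("dangling node id in *Intra section")

  st <- unique(data.table::data.table(
    phys = c(parts$pu, parts$pv), layer = c(parts$layer, parts$layer)))
  data.table::setorder(st, phys, layer)
  states <- data.table::data.table(
    name = phys$name[st$phys], layer = as.integer(st$layer),
    type = phys$type[st$phys], phys = st$phys)
  states[, state := .I]
  skey <- stats::setNames(states$state, paste(states$phys, states$layer))
  links <- data.table::data.table(
    layer = as.integer(parts$layer),
    u = skey[paste(parts$pu, parts$layer)],
    v = skey[paste(parts$pv, parts$layer)],
    w = parts$w)
  # orient cell-side first where types are known, for a stable layout
  swap <- states$type[links$u] == "genus" & states$type[links$v] == "cell"
  if (any(swap)) {
    tmp <- links$u[swap]
    links[swap, u := v]
    links[swap, v := tmp]
  }
  data.table::setorder(links, layer, u, v)
  new_ml_network(phys, states, links)
}
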