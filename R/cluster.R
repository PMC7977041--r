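#' Clustering parameters for the multilayer map equation
#'
#' @param relax_rate probability per step that the walker is guided by links
#'   in the current and adjacent layers rather than only the current layer;
#'   in `[0, 1]`, default 0.25.
#' @param relax_limit number of adjacent layers in each direction reachable
#'   when relaxing (default 1, i.e. temporal ordering of stages).
#' @param num_trials independent search trials; the minimum-codelength
#'   partition is returned (default 200).
#' @param seed integer seed; trial `k` uses `seed + k - 1`.
#' @param tolerance L1 convergence tolerance of the stationary-flow iteration.
#' @param multilevel recursively refine top modules into submodules when that
#'   lowers the total codelength (default TRUE).
#' @param sub_trials search trials per submodule refinement (default 10).
#' @param max_iter cap on power-iteration steps (default 10000).
#' @param level_margin optional parsimony margin in bits (default 0, i.e.
#'   pure codelength minimization). When positive, candidate module
#'   groupings within `level_margin` of the minimal codelength are treated
#'   as ties and the finest is reported; useful on near-degenerate
#'   codelength landscapes where coarse "shell" super-modules win by
#'   sub-millibit amounts.
#' @param physical_coding if TRUE (default), state nodes of the same physical
#'   node (i.e. the same genus) inside one module share a codeword, so the
#'   module codebook entropy is over merged physical visit rates; this is the
#'   codebook semantics under which long-lived assemblages are cheap to
#'   encode. With FALSE every state node gets its own codeword (then the
#'   one-module codelength equals the entropy of the state visit rates).
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(relax_rate = 0.25, relax_limit = 1L,
                           num_trials = 200L, seed = 1L,
                           tolerance = 1e-10, multilevel = TRUE,
                           sub_trials = 10L, max_iter = 10000L,
                           physical_coding = TRUE, level_margin = 0) {
  if (relax_rate < 0 || relax_rate > 1) stop("relax_rate must be in [0, 1]")
  if (relax_limit < 0) stop("relax_limit must be >= 0")
  if (num_trials < 1) stop("num_trials must be >= 1")
  structure(list(relax_rate = relax_rate, relax_limit = as.integer(relax_limit),
                 num_trials = as.integer(num_trials), seed = as.integer(seed),
                 tolerance = tolerance, multilevel = isTRUE(multilevel),
                 sub_trials = as.integer(sub_trials),
                 max_iter = as.integer(max_iter),
                 physical_coding = isTRUE(physical_coding),
                 level_margin = level_margin),
            class = "cluster_params")
}

#' Single-step transition distribution of the relax-rate walk
#'
#' Reference implementation of the walk dynamics, computed directly from the
#' definition: with probability `1 - r` the walker follows the weighted
#' intralayer links of the state's own layer; with probability `r` it first
#' picks a layer within `relax_limit` of the current one among the layers
#' where the physical node has links (proportionally to the node's strength
#' there), then follows that layer's links. A physical node with links only
#' in its own layer (every cell, by construction) renormalizes the relax mass
#' there.
#'
#' @param net `ml_network`.
#' @param params `cluster_params`.
#' @param state state-node id.
#' @return numeric vector over all state nodes, summing to 1.
#' @export
transition_distribution <- function(net, params, state) {
  stopifnot(inherits(net, "ml_network"), state >= 1, state <= nrow(net$states))
  r <- params$relax_rate
  S <- nrow(net$states)
  links <- rbind(net$links[, .(from = u, to = v, w)],
                 net$links[, .(from = v, to = u, w)])
  strength <- links[, .(s = sum(w)), keyby = from]
  s_of <- numeric(S); s_of[strength$from] <- strength$s

  this_phys <- net$states$phys[state]
  this_layer <- net$states$layer[state]
  sibs <- net$states[phys == this_phys]
  window <- sibs[abs(layer - this_layer) <= params$relax_limit]

  out <- numeric(S)
  intralayer <- links[from == state]
  out[intralayer$to] <- out[intralayer$to] +
    (1 - r) * intralayer$w / s_of[state]
  if (r > 0) {
    s_win <- sum(s_of[window$state])
    for (i in seq_len(nrow(window))) {
      st_i <- window$state[i]
      lk <- links[from == st_i]
      out[lk$to] <- out[lk$to] + r * (s_of[st_i] / s_win) * lk$w / s_of[st_i]
    }
  } else {
    out[intralayer$to] <- intralayer$w / s_of[state]
  }
  out
}

#' Stationary visit rates and flow graph of the multilayer walk
#'
#' Builds the sparse one-step transition kernel of the relax-rate walk and
#' solves the stationary equations exactly (sparse LU per connected
#' component, with the normalization replacing one redundant balance
#' equation). A direct solve sidesteps two numerical traps of iterative
#' schemes on this kernel: the walk alternates between taxa and cells, so
#' plain power iteration is 2-periodic, and the layer chain mixes slowly, so
#' even the lazy iteration needs tens of thousands of steps at full scale.
#' The stationarity residual `||pK - p||_1` is verified against
#' `params$tolerance` (polished by lazy power iterations, up to
#' `params$max_iter`, in the unlikely case the direct solve is not already
#' far below it). Disconnected components receive flow mass proportional to
#' their total intralayer link weight. Flows on state-node pairs are
#' symmetrized: net flow across any cut vanishes at stationarity, so module
#' exit flows are unaffected.
#'
#' @param net `ml_network`.
#' @param params `cluster_params`.
#' @return list of class `ml_flow`: `p` (visit rate per state node), `edges`
#'   (`u`, `v`, `phi` undirected flow), `residual`, `component`.
#' @export
stationary_flow <- function(net, params = cluster_params()) {
  stopifnot(inherits(net, "ml_network"))
  S <- nrow(net$states)
  k <- ml_kernel_cpp(S, net$links$u - 1L, net$links$v - 1L, net$links$w,
                     net$states$layer, net$states$phys - 1L,
                     params$relax_rate, params$relax_limit)
  K <- Matrix::sparseMatrix(i = k$i, j = k$j, x = k$x, dims = c(S, S))

  # the walk strictly alternates between the two node types, so the balance
  # equations close on the cell states alone: p_cell is stationary for the
  # two-step kernel Kcg %*% Kgc, and p_genus = t(Kcg) %*% p_cell. Solving the
  # reduced system (one sparse LU per component, one redundant balance
  # equation pinned) is exact and far smaller than the full state space.
  is_cell <- net$states$type == "cell"
  ci <- which(is_cell)
  gi <- which(!is_cell)
  Kcg <- K[ci, gi, drop = FALSE]
  Kgc <- K[gi, ci, drop = FALSE]
  if (length(K@x) != length(Kcg@x) + length(Kgc@x))
    stop("internal error: walk is not strictly bipartite")
  M2 <- Kcg %*% Kgc

  p <- numeric(S)
  comp_cells <- split(seq_along(ci), k$component[ci])
  for (cc in names(comp_cells)) {
    idx <- comp_cells[[cc]]               # positions within ci
    mass <- k$component_mass[as.integer(cc)]
    x <- if (length(idx) == 1L) 1 else {
      A <- Matrix::t(M2[idx, idx, drop = FALSE]) -
        Matrix::Diagonal(length(idx))
      c(1, as.numeric(Matrix::solve(A[-1L, -1L, drop = FALSE],
                                    -A[-1L, 1L, drop = FALSE])))
    }
    x[x < 0] <- 0  # clip roundoff-level negatives
    pc <- numeric(length(ci)); pc[idx] <- x
    pg <- as.numeric(Matrix::t(Kcg) %*% pc)
    sel_g <- k$component[gi] == as.integer(cc)
    # each alternating step swaps sides, so cells and genera carry equal mass
    p[ci[idx]] <- pc[idx] * (mass / 2 / sum(pc[idx]))
    if (any(sel_g)) p[gi[sel_g]] <- pg[sel_g] * (mass / 2 / sum(pg[sel_g]))
  }

  residual <- sum(abs(as.numeric(p %*% K) - p))
  iter <- 0L
  while (residual > params$tolerance && iter < params$max_iter) {
    p <- 0.5 * p + 0.5 * as.numeric(p %*% K)
    residual <- sum(abs(as.numeric(p %*% K) - p))
    iter <- iter + 1L
  }
  if (residual > max(params$tolerance, 1e-8))
    stop(sprintf("stationary flow residual %g above tolerance", residual))

  # symmetrized flow per unordered state pair
  f <- data.table::data.table(u = pmin(k$i, k$j), v = pmax(k$i, k$j),
                              f = p[k$i] * k$x)
  edges <- f[, .(phi = sum(f) / 2), keyby = .(u, v)]

  structure(list(p = p, edges = edges, residual = residual,
                 component = k$component,
                 n_components = k$n_components),
            class = "ml_flow")
}

#' Cluster a multilayer network by codelength minimization
#'
#' Runs `num_trials` independent searches (Louvain-style local moves and
#' network aggregation, iterated with fine-tuning until the two-level
#' codelength stops improving; trial `k` is seeded `seed + k - 1`) and keeps
#' the minimum-codelength partition. With `multilevel = TRUE`, top modules
#' are recursively split into submodules whenever the hierarchical map
#' equation decreases. Top-level modules are numbered by decreasing flow
#' volume, so module 1 is always the largest.
#'
#' @param net `ml_network`.
#' @param params `cluster_params`.
#' @param flow optionally a precomputed [stationary_flow()] (must match
#'   `params`).
#' @return object of class `ml_partition`: a `data.table` with one row per
#'   state node (`state`, `name`, `type`, `phys`, `layer`, `flow`, `top`,
#'   `path`), with attributes `codelength` (bits), `trial_codelengths`,
#'   `params` and `flow`.
#' @export
ml_cluster <- function(net, params = cluster_params(), flow = NULL) {
  stopifnot(inherits(net, "ml_network"))
  if (is.null(flow)) flow <- stationary_flow(net, params)
  res <- infomap_cpp(length(flow$p), flow$p,
                     flow$edges$u, flow$edges$v, flow$edges$phi,
                     net$states$phys - 1L, params$physical_coding,
                     params$seed, params$num_trials,
                     params$multilevel, params$sub_trials,
                     params$level_margin %||% 0)
  paths <- res$paths
  path_str <- apply(paths, 1L, function(row) paste(row[row > 0L], collapse = ":"))
  part <- data.table::data.table(
    state = net$states$state, name = net$states$name,
    type = net$states$type, phys = net$states$phys,
    layer = net$states$layer, flow = flow$p,
    top = paths[, 1L], path = path_str)
  data.table::setattr(part, "codelength", res$codelength)
  data.table::setattr(part, "trial_codelengths", res$trial_codelengths)
  data.table::setattr(part, "params", params)
  data.table::setattr(part, "flow", flow)
  data.table::setattr(part, "n_layers", net$n_layers)
  data.table::setattr(part, "class", c("ml_partition", class(data.table::data.table())))
  part[]
}

#' @export
print.ml_partition <- function(x, ...) {
  tm <- top_modules(x)
  cat(sprintf("multilayer partition: %d state nodes, %d top-level modules (%d with >=1%% flow), L = %.6f bits\n",
              nrow(x), length(unique(x$top)), length(tm), attr(x, "codelength")))
  invisible(x)
}

#' Top-level modules carrying at least a given flow share
#'
#' Modules with at least `min_flow` of the total flow are the reported
#' mega-assemblages; smaller modules are listed separately.
#'
#' @param p `ml_partition`.
#' @param min_flow flow-share cutoff (default 0.01).
#' @return integer vector of top-module ids, ordered by decreasing flow.
#' @export
top_modules <- function(p, min_flow = 0.01) {
  fl <- p[, .(flow = sum(flow)), keyby = top]
  fl[flow >= min_flow * sum(flow), top]
}

#' State-node sets of top-level modules
#' @param p `ml_partition`.
#' @param modules top-module ids (default: all).
#' @return named list of integer state-id vectors.
#' @export
module_states <- function(p, modules = sort(unique(p$top))) {
  stats::setNames(lapply(modules, function(m) p$state[p$top == m]),
                  as.character(modules))
}

#' Map-equation codelength of a partition (reference implementation)
#'
#' Computes the multilevel map equation directly from its entropy definition,
#' module by module: every non-leaf module (including the root) pays an index
#' codebook at the rate of its children's entry flows plus its own exit, and
#' every leaf module pays a codebook over its members' visit rates and its
#' exit flow. With `physical_coding` (the default), member visit rates of
#' state nodes sharing a physical node are merged into one codeword first.
#' This implementation is independent of the C++ search engine and serves as
#' its cross-check.
#'
#' @param flow [stationary_flow()] result.
#' @param partition an `ml_partition` (or any table with `state`, `path` and,
#'   for physical coding, `phys`).
#' @param physical_coding merge same-physical-node states within a leaf
#'   module into one codeword (default TRUE; must match the setting the
#'   partition was produced with for a meaningful comparison).
#' @return codelength in bits.
#' @export
codelength <- function(flow, partition, physical_coding = TRUE) {
  stopifnot(inherits(flow, "ml_flow"))
  if (!all(c("state", "path") %in% names(partition)))
    stop("partition must carry 'state' and 'path' columns")
  if (nrow(partition) != length(flow$p))
    stop("partition and flow cover different state-node sets")
  paths <- strsplit(partition$path[order(partition$state)], ":", fixed = TRUE)
  p <- flow$p
  # all module prefixes
  prefix_of <- function(pa, d) paste(pa[seq_len(d)], collapse = ":")
  node_leaf <- vapply(paths, paste, "", collapse = ":")

  # exit flow per module: sum of phi on edges whose endpoints diverge above
  # or at the module's level
  q <- new.env(parent = emptyenv())
  addq <- function(key, val) assign(key, (get0(key, envir = q) %||% 0) + val, envir = q)
  eu <- flow$edges$u; ev <- flow$edges$v; phi <- flow$edges$phi
  for (i in seq_along(eu)) {
    pu <- paths[[eu[i]]]; pv <- paths[[ev[i]]]
    cp <- 0L
    while (cp < length(pu) && cp < length(pv) && pu[cp + 1L] == pv[cp + 1L])
      cp <- cp + 1L
    if (cp < length(pu))
      for (d in (cp + 1L):length(pu)) addq(prefix_of(pu, d), phi[i])
    if (cp < length(pv))
      for (d in (cp + 1L):length(pv)) addq(prefix_of(pv, d), phi[i])
  }
  qval <- function(key) get0(key, envir = q) %||% 0

  all_prefixes <- unique(unlist(lapply(paths, function(pa)
    vapply(seq_along(pa), function(d) prefix_of(pa, d), ""))))
  parent_of <- function(key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) "<root>"
    else paste(parts[-length(parts)], collapse = ":")
  }
  children <- split(all_prefixes, vapply(all_prefixes, parent_of, ""))
  leaves <- setdiff(all_prefixes, names(children))

  Hterm <- function(rates) {
    tot <- sum(rates)
    if (tot <= 0) return(0)
    pr <- rates[rates > 0] / tot
    -tot * sum(pr * log2(pr))
  }

  L <- 0
  # root index codebook (no exit at the root)
  L <- L + Hterm(vapply(children[["<root>"]], qval, 0))
  for (key in setdiff(names(children), "<root>")) {
    L <- L + Hterm(c(vapply(children[[key]], qval, 0), qval(key)))
  }
  ord <- order(partition$state)
  phys_ord <- if (physical_coding && !is.null(partition$phys))
    partition$phys[ord] else seq_along(paths)
  for (key in leaves) {
    sel <- node_leaf == key
    # one codeword per physical node within the leaf module
    members <- vapply(split(p[sel], phys_ord[sel]), sum, 0)
    L <- L + Hterm(c(members, qval(key)))
  }
  L
}

#' Write a partition in tree text form
#'
#' One line per state node: `module_path flow "name" state_id physical_id
#' layer_id`, with the colon-separated module path sorted lexicographically
#' by path components (numeric) and flow descending within a leaf module.
#' Flows are visit rates and sum to 1 over the file. Output is deterministic
#' and byte-identical for a fixed partition.
#'
#' @param p `ml_partition`.
#' @param path output file.
#' @export
write_partition_tree <- function(p, path) {
  if (is.null(p$flow)) stop("partition lacks flows")
  dt <- data.table::as.data.table(p)[, .(path, flow, name, state, phys, layer)]
  comps <- strsplit(dt$path, ":", fixed = TRUE)
  maxd <- max(lengths(comps))
  for (d in seq_len(maxd)) {
    dt[, paste0(".d", d) := vapply(comps, function(x)
      if (length(x) >= d) as.integer(x[d]) else 0L, 0L)]
  }
  data.table::setorderv(dt, c(paste0(".d", seq_len(maxd)), "flow", "state"),
                        order = c(rep(1L, maxd), -1L, 1L))
  lines <- sprintf("%s %.15g \"%s\" %d %d %d",
                   dt$path, dt$flow, dt$name, dt$state, dt$phys, dt$layer)
  writeLines(lines, path)
  invisible(path)
}

#' Read a partition tree file
#' @param path file written by [write_partition_tree()].
#' @return data.table with `path`, `flow`, `name`, `state`, `phys`, `layer`,
#'   `top`, ordered by `state`.
#' @export
read_partition_tree <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines, regexec(
    "^([0-9:]+) ([-+0-9.eE]+) \"(.*)\" ([0-9]+) ([0-9]+) ([0-9]+)$", lines))
  if (any(lengths(m) != 7L)) stop("malformed tree line(s)")
  dt <- data.table::data.table(
    path = vapply(m, `[`, "", 2L),
    flow = as.numeric(vapply(m, `[`, "", 3L)),
    name = vapply(m, `[`, "", 4L),
    state = as.integer(vapply(m, `[`, "", 5L)),
    phys = as.integer(vapply(m, `[`, "", 6L)),
    layer = as.integer(vapply(m, `[`, "", 7L)))
  dt[, top := as.integer(sub(":.*$", "", path))]
  data.table::setorder(dt, state)
  dt[]
}

#' Robustness of the partition to the relax rate
#'
#' Clusters the network for each requested relax rate and reports the mean
#' best-match Jaccard similarity (over top-level modules, state-node sets)
#' against the solution at the reference rate (0.25).
#'
#' @param net `ml_network`.
#' @param rates numeric vector of relax rates in `[0, 1]`.
#' @param params base `cluster_params` (its `relax_rate` gives the reference).
#' @return data.table with one row per rate: `relax_rate`, `mean_jaccard`.
#' @export
relax_rate_sweep <- function(net, rates, params = cluster_params()) {
  stopifnot(all(rates >= 0 & rates <= 1))
  ref <- ml_cluster(net, params)
  ref_modules <- module_states(ref, top_modules(ref))
  out <- lapply(rates, function(r) {
    p_r <- if (identical(r, params$relax_rate)) ref else {
      pr <- params; pr$relax_rate <- r
      ml_cluster(net, pr)
    }
    sims <- vapply(ref_modules, function(ms)
      best_match_jaccard(ms, p_r)$similarity, 0)
    data.table::data.table(relax_rate = r, mean_jaccard = mean(sims))
  })
  data.table::rbindlist(out)
}
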