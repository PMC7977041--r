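#' Truncated Poisson draws on [1, upper]
#'
#' Draws integers with probability proportional to the Poisson(`mean`) mass
#' restricted to `1..upper` (inverse CDF over the finite support). This is
#' the resampling kernel of the parametric bootstrap: the support never
#' includes 0, so a recorded occurrence is never resampled away ("avoiding
#' false negatives"), and never exceeds the number of collections in the
#' cell.
#'
#' @param n number of draws.
#' @param mean Poisson mean (the observed occurrence count); must satisfy
#'   `1 <= mean <= upper`.
#' @param upper total collections in the grid cell.
#' @return integer vector of draws in `[1, upper]`.
#' @export
rtrunc_poisson <- function(n, mean, upper) {
  if (mean < 1 || mean > upper) stop("need 1 <= mean <= upper")
  if (upper == 1L) return(rep(1L, n))
  pmf <- stats::dpois(seq_len(upper), mean)
  sample.int(upper, n, replace = TRUE, prob = pmf)
}

# analytic mean of the truncated Poisson on [1, upper]
trunc_poisson_mean <- function(mean, upper) {
  k <- seq_len(upper)
  pmf <- stats::dpois(k, mean)
  sum(k * pmf) / sum(pmf)
}

#' Parametric bootstrap replicate of the assembled network
#'
#' Keeps the node and link sets of [assemble_network()] exactly and replaces
#' every link weight `n/N` by `n*/N` with `n*` drawn from the truncated
#' Poisson on `[1, N]` with mean `n`. Reproducible from `seed`.
#'
#' @param agg aggregated (merged) counts.
#' @param seed integer seed.
#' @return `ml_network` with resampled weights.
#' @export
resample_network <- function(agg, seed) {
  net <- if (inherits(agg, "ml_network")) agg else assemble_network(agg)
  if (is.null(net$links$n) || is.null(net$links$N))
    stop("network lacks the occurrence counts needed for resampling")
  n <- net$links$n
  N <- net$links$N
  drawn <- with_seed(seed, {
    out <- integer(length(n))
    grp <- paste(n, N)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      out[idx] <- rtrunc_poisson(length(idx), n[idx[1L]], N[idx[1L]])
    }
    out
  })
  net$links <- data.table::copy(net$links)
  net$links[, w := drawn / N]
  net
}

#' Bootstrap ensemble of clustered replicates
#'
#' Generates `replicates` truncated-Poisson resampled networks and clusters
#' each with the given parameters (by default a lighter search than the
#' reference: `num_trials` is taken from `params`). Replicate `k` uses
#' resampling seed `seed + k` and search seed `seed + 1000 + k`.
#'
#' @param agg aggregated (merged) counts the reference network was built from.
#' @param params `cluster_params` for the replicate searches (a smaller
#'   `num_trials` than the reference run, default 20, keeps the ensemble
#'   tractable).
#' @param replicates number of bootstrap replicates (default 100).
#' @param seed base seed.
#' @param dir optional directory: each replicate partition is also written as
#'   a tree file `bootstrap_<k>.tree` plus a JSON-lines `manifest.jsonl`.
#' @return list of class `bootstrap_ensemble` with elements `partitions`
#'   (list of `ml_partition`), `seeds`, `params`.
#' @export
bootstrap_ensemble <- function(agg, params = cluster_params(num_trials = 20L),
                               replicates = 100L, seed = 1L, dir = NULL) {
  if (replicates < 1L) stop("replicates must be >= 1")
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seeds <- seed + seq_len(replicates)
  partitions <- vector("list", replicates)
  manifest <- character(replicates)
  base_net <- if (inherits(agg, "ml_network")) agg else assemble_network(agg)
  for (k in seq_len(replicates)) {
    bnet <- resample_network(base_net, seeds[k])
    pk <- params
    pk$seed <- as.integer(seed + 1000L + k)
    part <- ml_cluster(bnet, pk)
    partitions[[k]] <- part
    if (!is.null(dir)) {
      write_partition_tree(part, file.path(dir, sprintf("bootstrap_%03d.tree", k)))
      manifest[k] <- jsonlite::toJSON(list(
        replicate = k, resample_seed = seeds[k], search_seed = pk$seed,
        codelength = attr(part, "codelength"),
        n_top_modules = length(unique(part$top))), auto_unbox = TRUE)
    }
  }
  if (!is.null(dir)) writeLines(manifest, file.path(dir, "manifest.jsonl"))
  structure(list(partitions = partitions, seeds = seeds, params = params),
            class = "bootstrap_ensemble")
}

#' Best-matching module by Jaccard similarity
#'
#' Finds the top-level module of `p` with the highest Jaccard similarity
#' (over state-node sets) to a reference module; ties are broken toward the
#' larger module, then the smaller module id.
#'
#' @param reference_states integer vector of state ids (a reference module).
#' @param p partition to search (an `ml_partition` or tree table with
#'   `state` and `top`).
#' @return list with `module` (id in `p`) and `similarity`.
#' @export
best_match_jaccard <- function(reference_states, p) {
  if (length(reference_states) == 0L) stop("empty reference module")
  if (nrow(p) == 0L) stop("empty partition")
  mods <- split(p$state, p$top)
  sizes <- lengths(mods)
  inter <- vapply(mods, function(s) length(intersect(reference_states, s)), 0L)
  sim <- inter / (length(reference_states) + sizes - inter)
  best <- order(-sim, -sizes, as.integer(names(mods)))[1L]
  list(module = as.integer(names(mods)[best]), similarity = unname(sim[best]))
}

#' Module support across a bootstrap ensemble (P05 / P07)
#'
#' For each top-level reference module, the proportion of bootstrap
#' solutions containing a module with Jaccard similarity above 0.5 (`P05`)
#' and above 0.7 (`P07`). `P07 <= P05` by construction.
#'
#' @param reference reference `ml_partition`.
#' @param ensemble a [bootstrap_ensemble()] (or plain list of partitions).
#' @param min_flow flow cutoff selecting the reference modules scored.
#' @return data.table with `module`, `P05`, `P07`.
#' @export
module_support <- function(reference, ensemble, min_flow = 0.01) {
  parts <- if (inherits(ensemble, "bootstrap_ensemble")) ensemble$partitions else ensemble
  mods <- top_modules(reference, min_flow)
  ref_sets <- module_states(reference, mods)
  sims <- vapply(parts, function(bp)
    vapply(ref_sets, function(ms) best_match_jaccard(ms, bp)$similarity, 0),
    numeric(length(mods)))
  sims <- matrix(sims, nrow = length(mods))
  data.table::data.table(module = mods,
                         P05 = rowMeans(sims > 0.5),
                         P07 = rowMeans(sims > 0.7))
}

#' Per-layer module significance
#'
#' For every state node, the fraction of bootstrap replicates in which it is
#' assigned to the module that best matches its reference module; reported
#' per layer as the median over the layer's state nodes. This is the
#' per-stage significance curve: a dip marks stages whose module membership
#' is unstable under resampling.
#'
#' @inheritParams module_support
#' @return data.table with `layer`, `median_probability`.
#' @export
per_layer_significance <- function(reference, ensemble, min_flow = 0.01) {
  parts <- if (inherits(ensemble, "bootstrap_ensemble")) ensemble$partitions else ensemble
  mods <- top_modules(reference, min_flow)
  ref_sets <- module_states(reference, mods)
  ref_mod_of <- reference$top[order(reference$state)]
  S <- nrow(reference)
  retained <- numeric(S)
  for (bp in parts) {
    bmod_of <- bp$top[order(bp$state)]
    match_of <- vapply(ref_sets, function(ms) best_match_jaccard(ms, bp)$module, 0L)
    names(match_of) <- as.character(mods)
    tgt <- match_of[as.character(ref_mod_of)]
    retained <- retained + as.numeric(!is.na(tgt) & bmod_of == tgt)
  }
  prob <- retained / length(parts)
  layer_of <- reference$layer[order(reference$state)]
  keep <- ref_mod_of %in% mods
  dt <- data.table::data.table(layer = layer_of[keep], prob = prob[keep])
  out <- dt[, .(median_probability = stats::median(prob)), keyby = layer]
  out[]
}
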