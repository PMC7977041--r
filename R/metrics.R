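#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected by its expectation under the permutation
#' model (hypergeometric marginals, Vinh et al.'s formula) and normalized by
#' `max(H(a), H(b))`:
#' `AMI = (MI - E[MI]) / (max(Ha, Hb) - E[MI])`.
#' Identical labelings give 1; a constant labeling gives 0 against anything
#' non-constant. Natural logs are used throughout (the base cancels).
#'
#' For partition-versus-timescale comparisons the units are state nodes, each
#' labeled by its top module on one side and its layer's era or period on the
#' other. An optional `weights` vector (e.g. flow volumes) reweights the
#' contingency table; weights are scaled to preserve the unit count so the
#' permutation-model correction stays defined.
#'
#' @param labels_a,labels_b equal-length vectors.
#' @param weights optional non-negative unit weights.
#' @return AMI in `[-eps, 1]`.
#' @export
ami <- function(labels_a, labels_b, weights = NULL) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must cover the same units (length mismatch)")
  n_units <- length(labels_a)
  if (n_units == 0L) stop("empty labelings")
  if (is.null(weights)) {
    tab <- table(labels_a, labels_b)
    M <- matrix(as.numeric(tab), nrow = nrow(tab))
  } else {
    stopifnot(length(weights) == n_units, all(weights >= 0))
    dt <- data.table::data.table(a = labels_a, b = labels_b, w = weights)
    tab <- data.table::dcast(dt[, .(w = sum(w)), by = .(a, b)], a ~ b,
                             value.var = "w", fill = 0)
    M <- as.matrix(tab[, -1L])
    # rescale so the effective unit count matches n (keeps E[MI] meaningful)
    M <- M * n_units / sum(M)
  }
  N <- sum(M)
  ai <- rowSums(M); bj <- colSums(M)
  Ha <- entropy_nats(ai / N)
  Hb <- entropy_nats(bj / N)
  if (Ha == 0 && Hb == 0) return(1)

  P <- M / N
  nz <- P > 0
  MI <- sum(P[nz] * log(P[nz] / (outer(ai / N, bj / N)[nz])))

  EMI <- expected_mi(ai, bj, N)
  denom <- max(Ha, Hb) - EMI
  if (denom <= .Machine$double.eps) return(0)
  (MI - EMI) / denom
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# E[MI] under the permutation (hypergeometric) model; marginals may be
# non-integer after weighting, in which case they are rounded.
expected_mi <- function(ai, bj, N) {
  ai <- round(ai); bj <- round(bj); N <- round(N)
  emi <- 0
  for (a in ai[ai > 0]) {
    for (b in bj[bj > 0]) {
      lo <- max(1, a + b - N)
      hi <- min(a, b)
      if (hi < lo) next
      nij <- lo:hi
      pr <- stats::dhyper(nij, a, N - a, b)
      emi <- emi + sum(pr * (nij / N) * log(N * nij / (a * b)))
    }
  }
  emi
}

#' Jaccard similarity of the genus sets of two modules
#'
#' A genus belongs to a module if any of its state nodes does; because state
#' nodes are layer-specific, genera can belong to several modules, making
#' assemblages taxonomically overlapping.
#'
#' @param p `ml_partition`.
#' @param module_a,module_b top-level module ids.
#' @return Jaccard index of the two genus sets.
#' @export
taxon_jaccard <- function(p, module_a, module_b) {
  known <- unique(p$top)
  if (!(module_a %in% known) || !(module_b %in% known))
    stop("unknown module id")
  ga <- unique(p$name[p$top == module_a & p$type == "genus"])
  gb <- unique(p$name[p$top == module_b & p$type == "genus"])
  length(intersect(ga, gb)) / length(union(ga, gb))
}

#' Genus set of a module
#' @param p `ml_partition`.
#' @param module top-level module id.
#' @export
module_genera <- function(p, module) {
  unique(p$name[p$top == module & p$type == "genus"])
}

#' Sorensen dissimilarity of two presence-absence sets
#'
#' `B_sor = (b + c) / (2a + b + c)` with `a = |A intersect B|`, `b = |A \\ B|`,
#' `c = |B \\ A|`; 0 for identical sets, 1 for disjoint ones.
#'
#' @param set_a,set_b vectors of taxon names.
#' @export
sorensen_dissimilarity <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0L && length(set_b) == 0L)
    stop("at least one set must be non-empty")
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  (b + cc) / (2 * a + b + cc)
}

#' Alluvial overlap tables between successive partitions
#'
#' For each adjacent pair of partitions over the same state-node set, the
#' module-by-module shared-node counts (the "streamlines" of an alluvial
#' diagram), sorted by module size. Marginals over the second partition
#' reproduce the first partition's module sizes.
#'
#' @param partitions ordered list of partitions (each with `state`, `top`).
#' @return list of data.tables, one per adjacent pair, with columns
#'   `module_a`, `module_b`, `shared`, `size_a`, `size_b`.
#' @export
alluvial_overlap <- function(partitions) {
  stopifnot(length(partitions) >= 2L)
  ref_states <- sort(partitions[[1L]]$state)
  for (p in partitions[-1L])
    if (!identical(sort(p$state), ref_states))
      stop("partitions cover different state-node sets")
  lapply(seq_len(length(partitions) - 1L), function(i) {
    a <- partitions[[i]]; b <- partitions[[i + 1L]]
    dt <- data.table::data.table(
      state = a$state[order(a$state)],
      module_a = a$top[order(a$state)],
      module_b = b$top[order(b$state)])
    out <- dt[, .(shared = .N), by = .(module_a, module_b)]
    sa <- dt[, .(size_a = .N), by = module_a]
    sb <- dt[, .(size_b = .N), by = module_b]
    out <- merge(merge(out, sa, by = "module_a"), sb, by = "module_b")
    data.table::setcolorder(out, c("module_a", "module_b", "shared", "size_a", "size_b"))
    data.table::setorder(out, -size_a, module_a, -shared)
    out[]
  })
}

#' Flow dominance of top modules through time, and transition detection
#'
#' Computes, per layer, each top-level module's share of that layer's total
#' state-node flow, and reports a biotic transition wherever the dominant
#' (argmax) module changes between consecutive layers. A transition is
#' labeled `"abrupt"` when the incoming module's share rises from below
#' `abrupt_low` to above `abrupt_high` within one layer, else
#' `"protracted"`.
#'
#' @param p `ml_partition` (carries per-state flow).
#' @param abrupt_low,abrupt_high share thresholds operationalizing abrupt vs
#'   protracted dominance shifts (defaults 0.25 / 0.75).
#' @param min_flow dominance is tracked over the major top-level modules
#'   (those holding at least this share of total flow, default 1%, matching
#'   the mega-assemblage reporting convention); shares are renormalized per
#'   layer over those modules.
#' @return list of class `dominance_timeline`: `shares` (data.table layer x
#'   module share), `dominant` (per-layer dominant module) and `transitions`
#'   (`after_layer`, `at_layer`, `from`, `to`, `style`, shares at the
#'   crossing).
#' @export
dominance_timeline <- function(p, abrupt_low = 0.25, abrupt_high = 0.75,
                               min_flow = 0.01) {
  stopifnot(inherits(p, "ml_partition") || all(c("layer", "top", "flow") %in% names(p)))
  totals <- p[, .(flow = sum(flow)), by = top]
  majors <- totals[flow >= min_flow * sum(flow), top]
  sh <- p[top %in% majors, .(flow = sum(flow)), by = .(layer, top)]
  sh[, share := flow / sum(flow), by = layer]
  data.table::setorder(sh, layer, top)
  dom <- sh[, .SD[which.max(share)], by = layer][order(layer)]
  layers <- dom$layer
  transitions <- list()
  for (i in seq_len(nrow(dom) - 1L)) {
    if (dom$top[i] != dom$top[i + 1L]) {
      incoming <- dom$top[i + 1L]
      share_before <- sh[layer == layers[i] & top == incoming, share]
      share_before <- if (length(share_before)) share_before else 0
      share_after <- dom$share[i + 1L]
      style <- if (share_before < abrupt_low && share_after > abrupt_high)
        "abrupt" else "protracted"
      transitions[[length(transitions) + 1L]] <- data.table::data.table(
        after_layer = layers[i], at_layer = layers[i + 1L],
        from = dom$top[i], to = incoming,
        share_before = share_before, share_after = share_after,
        style = style)
    }
  }
  transitions <- if (length(transitions)) data.table::rbindlist(transitions)
    else data.table::data.table(after_layer = integer(), at_layer = integer(),
                                from = integer(), to = integer(),
                                share_before = numeric(), share_after = numeric(),
                                style = character())
  structure(list(shares = sh[, .(layer, top, share)], dominant = dom[, .(layer, top, share)],
                 transitions = transitions),
            class = "dominance_timeline")
}

#' @export
print.dominance_timeline <- function(x, ...) {
  cat(sprintf("dominance timeline over %d layers, %d transition(s)\n",
              length(unique(x$shares$layer)), nrow(x$transitions)))
  if (nrow(x$transitions)) print(x$transitions)
  invisible(x)
}

#' Era/period labels per state node for timescale comparisons
#'
#' Maps every state node of a partition to the era (or period) of its layer,
#' for AMI against the geological timescale. When stages were merged into
#' layers, the label of the older constituent stage is used.
#'
#' @param p `ml_partition`.
#' @param ts timescale.
#' @param merge_map optional stage-to-layer map used during assembly.
#' @param level `"era"` or `"period"`.
#' @return character vector aligned with `p$state`.
#' @export
layer_labels <- function(p, ts, merge_map = NULL, level = c("era", "period")) {
  level <- match.arg(level)
  if (is.null(merge_map)) merge_map <- ts$stage_index
  # oldest constituent stage per layer
  lab <- ts[[level]][match(sort(unique(merge_map)),  merge_map)]
  lab[p$layer + 1L]
}
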