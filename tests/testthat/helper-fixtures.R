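# shared fixtures and independent oracles for the test suite

# small aggregated-count table: 2 stages, 2 cells, 2 genera
toy_agg <- function() {
  as_agg_counts(data.table::data.table(
    stage_index = c(0L, 0L, 0L, 1L, 1L, 1L),
    cell_id = c("q0r0", "q0r0", "q1r0", "q0r0", "q1r0", "q1r0"),
    genus = c("ga", "gb", "ga", "gb", "ga", "gb"),
    n_genus = c(2L, 1L, 3L, 1L, 2L, 2L),
    N_total = c(3L, 3L, 4L, 2L, 5L, 5L)))
}

# random small multilayer count tables for oracle fixtures; sized so the
# resulting network has at most `max_states` state nodes
random_small_agg <- function(seed, n_layers = 2, n_cells = 2, n_genera = 2,
                             max_states = 8) {
  set.seed(seed)
  repeat {
    rows <- list()
    for (l in seq_len(n_layers) - 1L) {
      for (ci in seq_len(n_cells)) {
        N <- sample(2:6, 1)
        present <- which(stats::runif(n_genera) < 0.7)
        if (length(present) == 0L) present <- sample.int(n_genera, 1)
        for (g in present) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            stage_index = l, cell_id = sprintf("q%dr0", ci),
            genus = sprintf("g%02d", g),
            n_genus = sample.int(N, 1), N_total = N)
        }
      }
    }
    agg <- as_agg_counts(data.table::rbindlist(rows))
    net <- assemble_network(agg)
    if (nrow(net$states) <= max_states) return(agg)
  }
}

# dense transition kernel assembled row by row from the reference
# single-step distribution (independent of the C++ kernel)
dense_kernel <- function(net, params) {
  S <- nrow(net$states)
  t(vapply(seq_len(S), function(s) transition_distribution(net, params, s),
           numeric(S)))
}

# stationary distribution of a dense kernel by long lazy iteration;
# disconnected pieces are seeded with mass proportional to their total
# intralayer link weight (components found by BFS on the kernel support)
dense_stationary <- function(K, net, iters = 20000) {
  S <- nrow(K)
  adj <- (K + t(K)) > 0
  comp <- rep(NA_integer_, S)
  nc <- 0L
  for (s in seq_len(S)) {
    if (!is.na(comp[s])) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  wcomp <- vapply(seq_len(nc), function(cc)
    sum(net$links$w[comp[net$links$u] == cc]), 0)
  x <- numeric(S)
  for (cc in seq_len(nc)) {
    idx <- comp == cc
    x[idx] <- (wcomp[cc] / sum(wcomp)) / sum(idx)
  }
  for (i in seq_len(iters)) x <- 0.5 * x + 0.5 * as.vector(x %*% K)
  x
}

# all set partitions of n elements as a list of assignment vectors
set_partitions <- function(n) {
  out <- list()
  gen <- function(assign, k, maxg) {
    if (k > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (g in seq_len(maxg + 1L)) {
      assign[k] <- g
      gen(assign, k + 1L, max(maxg, g))
    }
  }
  gen(integer(n), 1L, 0L)
  out
}

# two-level map-equation codelength from first principles (entropy terms),
# with optional physical-node codeword merging; independent of both the C++
# engine and the package's codelength()
two_level_L <- function(flow, assign, phys = seq_along(flow$p),
                        physical_coding = TRUE) {
  p <- flow$p
  ed <- flow$edges
  mods <- sort(unique(assign))
  H <- function(rates) {
    tot <- sum(rates)
    if (tot <= 0) return(0)
    pr <- rates[rates > 0] / tot
    -tot * sum(pr * log2(pr))
  }
  q <- vapply(mods, function(m) {
    inA <- assign[ed$u] == m
    inB <- assign[ed$v] == m
    sum(ed$phi[xor(inA, inB)])
  }, 0)
  L <- H(q)  # index codebook (no exit at the root)
  for (i in seq_along(mods)) {
    members <- which(assign == mods[i])
    masses <- if (physical_coding) vapply(split(p[members], phys[members]), sum, 0)
      else p[members]
    L <- L + H(c(masses, q[i]))
  }
  L
}

# exhaustive-enumeration minimum of the two-level codelength
enumeration_minimum <- function(net, params) {
  flow <- stationary_flow(net, params)
  phys <- net$states$phys
  parts <- set_partitions(length(flow$p))
  min(vapply(parts, function(a)
    two_level_L(flow, a, phys, params$physical_coding), 0))
}

# one shared run of the default planted-assemblage pipeline, cached for the
# whole test session
.pipeline_cache <- new.env(parent = emptyenv())
default_pipeline <- function() {
  if (!is.null(.pipeline_cache$run)) return(.pipeline_cache$run)
  rec <- generate_fossil_record(synth_config())
  agg <- aggregate_occurrences(rec$occurrences)
  net <- assemble_network(agg)
  params <- cluster_params(num_trials = 10L, seed = 1L)
  flow <- stationary_flow(net, params)
  part <- ml_cluster(net, params, flow = flow)
  .pipeline_cache$run <- list(rec = rec, agg = agg, net = net,
                              params = params, flow = flow, part = part)
  .pipeline_cache$run
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
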