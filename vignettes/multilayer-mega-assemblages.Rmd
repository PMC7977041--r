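---
title: "Delineating marine mega-assemblages with the multilayer map equation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating marine mega-assemblages with the multilayer map equation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the model and its
assumptions, the parameters that matter, what the synthetic generator does
and does not emulate, the numerical choices, and the design decisions taken
where the design was genuinely open.

## The network model

Stage-binned occurrence data have a natural bipartite structure: collections
record genera at places. We aggregate collections per geological stage onto
a hexagonal grid and connect genus $i$ to spatiotemporal cell $k$ with
weight
$$w_{ki} = \frac{n_{ki}}{N_k},$$
the fraction of cell $k$'s collections that record $i$. Weights are
recomputed after any stage merging (pooled $n$ over pooled $N$), because the
formula's semantics are collection counts, not an average of ratios.

Nodes are of two kinds. Genera are *multilayer physical nodes*: one state
node per stage in which the genus has links. Spatiotemporal cells are
single-layer nodes: an occupied (cell, stage) pair is its own node. This
convention follows the bookkeeping of the assembled empirical network (total
nodes = genera + occupied spatiotemporal cells) and means temporal coupling
flows exclusively through genera.

## Walk dynamics and the relax rate

A random walker at state $(i, t)$ follows intralayer links with probability
$1-r$, and with probability $r$ "relaxes": it chooses a layer within the
relax limit (default 1) of $t$, among layers where $i$ has links,
proportionally to $i$'s strength there, then follows that layer's links. A
node with links only in its own layer — every cell — renormalizes the relax
mass there. The defaults $r = 0.25$ and relax limit 1 balance temporal
coupling against intralayer geographic structure, and make layer order
matter: the walker can only drift one stage per relax event.

Two numerical facts shape the implementation:

* the walk alternates strictly between taxa and cells, so plain power
  iteration is 2-periodic and never converges;
* the 40-to-99-layer chain mixes slowly (spectral gap $\sim r/t^2$), so even
  a lazy iteration needs tens of thousands of sweeps at full scale.

Both are avoided by solving the stationary balance equations exactly. The
bipartite alternation closes the equations on the cell states alone
($p_\text{cell}$ is stationary for the two-step kernel
$K_{cg}K_{gc}$), giving one sparse LU solve per connected component on a
matrix the size of the cell set; genus rates follow by one multiplication.
One redundant balance equation per component is pinned rather than replaced
by a dense normalization row (which would destroy sparse fill). Components
get flow mass proportional to their total link weight — a teleportation-free
convention, because the method never mentions teleportation. The stationarity
residual $\lVert pK - p\rVert_1$ is checked (typically $10^{-15}$).

Flows between state pairs are symmetrized; at stationarity the net flow
across any cut vanishes, so all module enter/exit rates are unchanged by
symmetrization.

## The map equation and physical-node coding

Partitions are scored by the multilevel map equation: every index codebook
(the root and every super-module) pays for child-enter events and its own
exit, every leaf module pays for member visits and its exit. Within a
module, the state nodes of one genus share a codeword, so a module's
codebook entropy is over *merged physical* visit rates ("physical coding").
This choice is load-bearing: with one codeword per state node, every extra
layer in a module adds codewords for all its members, and the codelength
optimum of a stage-structured record degenerates into per-layer modules —
on planted data the one-layer partition then beats the planted blocks by a
wide margin, while physical coding reverses the ordering.
`physical_coding = FALSE`
restores plain state coding, under which the one-module codelength equals
the entropy of the state visit rates — the variant used by some of the
package's own oracle tests.

## Search

The two-level search is Louvain-style: seeded trials (half from singletons,
half from random edge-contraction coarsenings, which matters on chain-like
graphs where pairwise merges away from the chain ends are locally uphill),
local moves with exact $\Delta L$, aggregation ladders, and fine-tuning
until the codelength stops improving. Ties in $\Delta L$ keep the current
module, and all randomness comes from an internal deterministic generator,
so a fixed seed yields a byte-identical partition.

The hierarchy is then built in both directions. Downward, top modules are
recursively split into submodules whenever that lowers the total
codelength. Upward, an index tree is constructed over the two-level modules:
candidate groupings of each index node's children come from (a) clustering
the module graph whose node flows are the modules' boundary rates, with
singleton groups transparent (an ungrouped module stays a direct child and
pays no intermediate codebook), and (b) deterministic max-flow agglomeration
cuts. Each candidate is scored with *look-ahead*: the exact index cost with
the candidate's groups recursively optimized inside. Look-ahead matters
because a super-module is often only worth its codebook once its interior is
nested — scored flat, it is wrongly rejected. A work budget caps the
recursion on pathological inputs. `level_margin` (default 0, pure
minimization) optionally treats groupings within a margin of the minimum as
ties and keeps the finest; useful on near-degenerate landscapes where
"shell" super-modules win by sub-millibit amounts.

Mega-assemblages are reported as top-level modules carrying at least 1% of
the flow; smaller top-level modules are listed separately (the flow cutoff
is a reporting convention, not part of the objective).

## The synthetic generator

`synth_config()` plants $A$ assemblages — disjoint genus pools up to a
`taxon_sharing` fraction of boundary-crossing survivor taxa that straddle
each boundary by 1–3 layers — over `n_layers` stages. Genus ranges are
contiguous, with length uniform on `[range_coverage * span, span]` of the
assemblage's span; high coverage keeps assemblages internally cohesive,
which is the point of a planted-recovery benchmark. Sampling emulates
collection-based data: Poisson collection counts per (stage, cell),
Bernoulli cell entry (`cell_occupancy`), binomial detection within a cell's
collections (`occupancy`). Dominance shifts are abrupt (one-layer) by
default; `styles = "protracted"` mixes the two pools' cell residency
linearly over `ramp_length` layers, with activity spans extended half a ramp
on each side.

Default calibration, chosen once from the empirical record's own statistics:
~16 collections per occupied spatiotemporal cell motivates
`collections_per_cell = 12`; roughly eight occupied (cell, stage) pairs per
genus across its range, against ~50 cells per stage, implies genera occupy a
few percent of cells per stage, motivating `cell_occupancy = 0.1` (3 of 30
cells). An early draft used 0.25; that makes every genus cosmopolitan,
halves the contrast between within-layer and between-layer structure, and
pushes the codelength landscape into a near-degenerate regime where the
top-level module scale is undetermined to within sub-millibit codelength
differences — worth knowing
if you explore parameters: with planted spans near the map equation's
natural module scale, tiny data perturbations legitimately flip the top
level.

What the generator does **not** emulate: spatial autocorrelation between
cells (cells are exchangeable within a layer unless `provinces = 2`, which
plants two provinces with partially province-restricted pools to exercise
lower hierarchy levels), empirical abundance distributions, secular sampling
trends, and paleocoordinate uncertainty. Passing tests on this generator
demonstrate the machinery recovers planted structure of realistic shape and
strength; they do not certify behaviour under every pathology of the real
record.

## The bootstrap and its limits at desk scale

Link weights are resampled as $n^\ast/N$ with $n^\ast$ truncated-Poisson on
$[1, N]$ with mean $n$ — the support excludes zero, so no link is ever lost.
Each replicate is re-clustered (by default with fewer trials than the
reference, a documented tractability knob) and compared to the reference by
best-match Jaccard over top-level state-node sets; per-state retention rates
are summarized per layer by their median.

A property of this scheme worth stating plainly: for $n = 1$ (most fossil
links) the truncated mean exceeds 1 substantially, so resampling
systematically inflates weak links relative to strong ones. On desk-scale
synthetic networks, where top-level structure is decided by small codelength
margins over cuts crossed by few links, this perturbation routinely
fragments or regroups the larger modules: per-module support values
(P05/P07) well below 1 for the widest planted assemblage are an honest
property of the method at this scale, not a bug. On networks the size of the
empirical record, cuts are crossed by orders of magnitude more links and the
same statistics are far more stable. The per-stage significance curve
remains informative at desk scale: membership probability dips at noisy
(protracted) transitions relative to assemblage interiors.

## Partition comparison

`ami()` computes adjusted mutual information with the hypergeometric
(permutation-model) expectation and max-entropy normalization; natural logs
throughout (the base cancels). For partition-versus-timescale comparisons
the units are state nodes, labeled by top module on one side and by their
layer's era or period on the other (merged layers take the older
constituent's label); a flow-weighted option rescales the contingency table
while preserving the unit count. `taxon_jaccard()` works on genus sets — a
genus belongs to every module that contains one of its state nodes, so
assemblages can overlap taxonomically. Sørensen dissimilarity
$(b+c)/(2a+b+c)$, alluvial overlap tables and the dominance timeline (module
flow shares per layer; a transition is "abrupt" when the incoming module's
share crosses from below 0.25 to above 0.75 within one layer, else
"protracted" — configurable thresholds operationalizing qualitative labels)
complete the comparison toolkit.

## Problem sizes and determinism

The packaged experiments run the default 40-layer, ~1150-genus, 30-cell
configuration (about 11,000 state nodes and 30,000 links; clustering takes
seconds) and 12–20 bootstrap replicates; these sizes were chosen so the
full test suite and the acceptance script each complete comfortably on a
single CPU. All stochastic steps — generator, trials, resampling — are
keyed to explicit seeds, and equal seeds reproduce byte-identical outputs.

## Known limitations

* The search is heuristic; only networks small enough for exhaustive
  enumeration carry an optimality guarantee (the oracle tests).
* The hierarchical index construction explores candidate groupings from two
  proposal families; other near-optimal hierarchies with different top-level
  module counts can exist within fractions of a millibit on degenerate
  landscapes (see `level_margin`).
* Protracted dominance shifts genuinely couple the two assemblages they
  join; at desk scale the map equation may prefer a merged top-level module
  across such a ramp. The dominance timeline still localizes the shift.
* The hex tessellation treats coordinates as planar degrees, matching the
  "degrees latitude–longitude" convention of the binning it reimplements;
  cells are not equal-area, and the dateline is handled by nearest-centre
  assignment with longitude wrap rather than a seamless wrap of the
  tessellation itself (the column spacing does not divide 360°).
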