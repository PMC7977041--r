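// Core numerics for fossilflows:
//  - sparse transition kernel of the relax-rate multilayer random walk
//    (the stationary solve happens in R on the sparse matrix)
//  - Louvain-style minimization of the (multilevel) map equation over the
//    symmetrized stationary flow graph

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <map>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <functional>

using namespace Rcpp;

static inline double plogp(double x) {
  return (x > 1e-300) ? x * std::log2(x) : 0.0;
}

// ---------------------------------------------------------------------------
// deterministic RNG (64-bit splitmix + bounded draw), stable across platforms
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n)
  int below(int n) {
    if (n <= 1) return 0;
    uint64_t lim = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    uint64_t x;
    do { x = next(); } while (x >= lim);
    return (int)(x % (uint64_t)n);
  }
  void shuffle(std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = below(i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

// ---------------------------------------------------------------------------
// stationary flow of the relax-rate multilayer walk
// ---------------------------------------------------------------------------

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) { while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) parent[a] = b; }
};

// Sparse transition kernel of the relax-rate walk, as triplets, plus the
// connected components of the coupled dynamics and per-component link mass.
// [[Rcpp::export]]
List ml_kernel_cpp(int n_states,
                   IntegerVector link_u, IntegerVector link_v, NumericVector link_w,
                   IntegerVector state_layer, IntegerVector state_phys,
                   double relax_rate, int relax_limit) {
  const int S = n_states;
  const int M = link_u.size();
  const double r = relax_rate;

  // state adjacency (CSR over intralayer links, both directions)
  std::vector<int> adeg(S, 0);
  for (int l = 0; l < M; ++l) { adeg[link_u[l]]++; adeg[link_v[l]]++; }
  std::vector<int> aoff(S + 1, 0);
  for (int i = 0; i < S; ++i) aoff[i + 1] = aoff[i] + adeg[i];
  std::vector<int> anbr(aoff[S]);
  std::vector<double> awt(aoff[S]);
  {
    std::vector<int> pos(aoff.begin(), aoff.end() - 1);
    for (int l = 0; l < M; ++l) {
      int u = link_u[l], v = link_v[l]; double w = link_w[l];
      anbr[pos[u]] = v; awt[pos[u]++] = w;
      anbr[pos[v]] = u; awt[pos[v]++] = w;
    }
  }
  std::vector<double> strength(S, 0.0);
  for (int i = 0; i < S; ++i)
    for (int k = aoff[i]; k < aoff[i + 1]; ++k) strength[i] += awt[k];
  for (int i = 0; i < S; ++i)
    if (strength[i] <= 0) stop("state node %d has no intralayer link", i + 1);

  // group states by physical node, sorted by layer
  int P = 0;
  for (int i = 0; i < S; ++i) P = std::max(P, state_phys[i] + 1);
  std::vector<std::vector<int>> phys_states(P);
  for (int i = 0; i < S; ++i) phys_states[state_phys[i]].push_back(i);
  for (int p = 0; p < P; ++p)
    std::sort(phys_states[p].begin(), phys_states[p].end(),
              [&](int a, int b) { return state_layer[a] < state_layer[b]; });

  // per (phys, state) relax window [jlo, jhi] over the phys's state list,
  // and the window strength sum
  std::vector<int> wlo(S), whi(S);
  std::vector<double> wsum(S);
  for (int p = 0; p < P; ++p) {
    const std::vector<int>& st = phys_states[p];
    int k = (int)st.size();
    for (int i = 0; i < k; ++i) {
      int lo = i, hi = i;
      while (lo > 0 && state_layer[st[i]] - state_layer[st[lo - 1]] <= relax_limit) --lo;
      while (hi + 1 < k && state_layer[st[hi + 1]] - state_layer[st[i]] <= relax_limit) ++hi;
      double ssum = 0.0;
      for (int j = lo; j <= hi; ++j) ssum += strength[st[j]];
      wlo[st[i]] = lo; whi[st[i]] = hi; wsum[st[i]] = ssum;
    }
  }

  // connected components under the coupled dynamics
  UnionFind uf(S);
  for (int l = 0; l < M; ++l) uf.unite(link_u[l], link_v[l]);
  if (r > 0) {
    for (int p = 0; p < P; ++p) {
      const std::vector<int>& st = phys_states[p];
      for (size_t i = 1; i < st.size(); ++i)
        if (state_layer[st[i]] - state_layer[st[i - 1]] <= relax_limit)
          uf.unite(st[i], st[i - 1]);
    }
  }
  std::vector<int> comp(S);
  std::unordered_map<int, int> roots;
  int n_comp = 0;
  for (int i = 0; i < S; ++i) {
    int rt = uf.find(i);
    auto it = roots.find(rt);
    if (it == roots.end()) { roots[rt] = n_comp; comp[i] = n_comp; ++n_comp; }
    else comp[i] = it->second;
  }
  // component mass proportional to total intralayer link weight
  std::vector<double> cmass(n_comp, 0.0);
  double wtot = 0.0;
  for (int l = 0; l < M; ++l) { cmass[comp[link_u[l]]] += link_w[l]; wtot += link_w[l]; }
  for (int c = 0; c < n_comp; ++c) cmass[c] /= wtot;

  // kernel triplets: entry (alpha -> beta) with probability
  // c_{i,j} * w / s_j for each link of the physical node in the target layer
  std::vector<int> ki, kj;
  std::vector<double> kx;
  size_t nnz_guess = (size_t)M * 2 * (2 * relax_limit + 1);
  ki.reserve(nnz_guess); kj.reserve(nnz_guess); kx.reserve(nnz_guess);
  for (int p = 0; p < P; ++p) {
    const std::vector<int>& st = phys_states[p];
    int k = (int)st.size();
    for (int i = 0; i < k; ++i) {
      int si = st[i];
      int lo = wlo[si], hi = whi[si];
      bool own_only = (r == 0.0) || (lo == i && hi == i);
      int jlo = own_only ? i : lo, jhi = own_only ? i : hi;
      for (int j = jlo; j <= jhi; ++j) {
        double cij = own_only ? 1.0
          : ((j == i) ? (1.0 - r) : 0.0) + r * strength[st[j]] / wsum[si];
        if (cij == 0.0) continue;
        int sj = st[j];
        double scale = cij / strength[sj];
        for (int e = aoff[sj]; e < aoff[sj + 1]; ++e) {
          ki.push_back(si + 1);
          kj.push_back(anbr[e] + 1);
          kx.push_back(scale * awt[e]);
        }
      }
    }
  }

  IntegerVector compv(S);
  for (int i = 0; i < S; ++i) compv[i] = comp[i] + 1;
  NumericVector cmassv(n_comp);
  for (int c = 0; c < n_comp; ++c) cmassv[c] = cmass[c];
  NumericVector strv(S);
  for (int i = 0; i < S; ++i) strv[i] = strength[i];

  return List::create(_["i"] = wrap(ki), _["j"] = wrap(kj), _["x"] = wrap(kx),
                      _["component"] = compv, _["component_mass"] = cmassv,
                      _["strength"] = strv, _["n_components"] = n_comp);
}

// ---------------------------------------------------------------------------
// map-equation search (two-level optimizer + recursive multilevel refinement)
//
// Codebook semantics: with physical coding (the default used for multilayer
// runs), state nodes of the same physical node inside one module share a
// codeword, so a module's codebook entropy is over merged physical visit
// rates plus the exit; turning physical coding off is equivalent to giving
// every state node its own physical id.
// ---------------------------------------------------------------------------

struct FlowNet {
  int n = 0;
  std::vector<double> p;    // node flow (visit rate mass)
  std::vector<double> e;    // flow from node to outside this (sub)network
  double exitC = 0.0;       // total exit flow of the enclosing module
  std::vector<int> eu, ev;  // undirected flow edges (each once)
  std::vector<double> phi;
  // per node: (physical id, mass) contributions for codebook merging
  std::vector<std::vector<std::pair<int, double>>> npm;
  // child entities represented by each node (for singleton transparency at
  // the super-module level); 1 at any base level
  std::vector<int> nsize;
  // CSR built on demand
  std::vector<int> off, nbr;
  std::vector<double> wt;
  std::vector<double> deg;  // sum of incident phi + e

  void build_csr() {
    std::vector<int> d(n, 0);
    for (size_t l = 0; l < eu.size(); ++l) { d[eu[l]]++; d[ev[l]]++; }
    off.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) off[i + 1] = off[i] + d[i];
    nbr.assign(off[n], 0);
    wt.assign(off[n], 0.0);
    std::vector<int> pos(off.begin(), off.end() - 1);
    for (size_t l = 0; l < eu.size(); ++l) {
      int u = eu[l], v = ev[l]; double w = phi[l];
      nbr[pos[u]] = v; wt[pos[u]++] = w;
      nbr[pos[v]] = u; wt[pos[v]++] = w;
    }
    deg.assign(n, 0.0);
    for (int i = 0; i < n; ++i) {
      deg[i] = e[i];
      for (int k = off[i]; k < off[i + 1]; ++k) deg[i] += wt[k];
    }
  }
};

// partition bookkeeping for local moves; objective
//   J = plogp(sumQ + exitC) - 2 sum_M plogp(q_M)
//       + sum_M plogp(q_M + ps_M) - sum_{M,phys} plogp(mass_{M,phys})
struct MoveState {
  std::vector<int> mod;
  std::vector<double> q, ps;
  std::vector<int> msize;
  double sumQ = 0.0;
  std::vector<int> freelist;
  // merged physical masses per (module, phys)
  std::unordered_map<uint64_t, double> pm;
  double physTerm = 0.0;
  uint64_t P = 0;  // phys id stride
  // super-module search: a singleton group is transparent (its member stays
  // a direct child of the enclosing codebook, paying no intermediate index)
  bool transparent_singletons = false;

  // codebook contribution of one module given its boundary flow, member flow
  // sum and size (excluding the +plogp(sumQ) total-rate term)
  inline double mod_term(double qm, double psm, int size) const {
    if (size <= 0) return 0.0;
    // a singleton group is transparent: its child's root entry -plogp(q) is
    // already carried by the (constant) physTerm bookkeeping
    if (transparent_singletons && size == 1) return 0.0;
    return -2.0 * plogp(qm) + plogp(qm + psm);
  }

  inline uint64_t key(int m, int g) const { return (uint64_t)m * P + (uint64_t)g; }
  inline double mass(int m, int g) const {
    auto it = pm.find(key(m, g));
    return it == pm.end() ? 0.0 : it->second;
  }

  std::vector<int> osize;  // child-entity counts (transparency granularity)

  void init_from(const FlowNet& net, const std::vector<int>& assignment,
                 int n_modules, uint64_t phys_stride) {
    P = phys_stride;
    mod = assignment;
    q.assign(n_modules, 0.0);
    ps.assign(n_modules, 0.0);
    msize.assign(n_modules, 0);
    osize.assign(n_modules, 0);
    freelist.clear();
    pm.clear();
    for (int i = 0; i < net.n; ++i) {
      q[mod[i]] += net.deg[i];
      ps[mod[i]] += net.p[i];
      msize[mod[i]]++;
      osize[mod[i]] += net.nsize[i];
      for (const auto& gm : net.npm[i]) pm[key(mod[i], gm.first)] += gm.second;
    }
    for (size_t l = 0; l < net.eu.size(); ++l)
      if (mod[net.eu[l]] == mod[net.ev[l]]) q[mod[net.eu[l]]] -= 2.0 * net.phi[l];
    sumQ = 0.0;
    for (size_t m = 0; m < q.size(); ++m) {
      if (q[m] < 0 && q[m] > -1e-12) q[m] = 0;
      sumQ += q[m];
      if (msize[m] == 0) freelist.push_back((int)m);
    }
    physTerm = 0.0;
    for (const auto& kv : pm) physTerm += plogp(kv.second);
  }

  double objective(double exitC) const {
    double s = 0.0;
    for (size_t m = 0; m < q.size(); ++m)
      s += mod_term(q[m], ps[m], osize[m]);
    return plogp(sumQ + exitC) + s - physTerm;
  }

  // change in physTerm if node with contributions `gm` moves from A to B
  double phys_delta(const std::vector<std::pair<int, double>>& gm, int A, int B) const {
    double d = 0.0;
    for (const auto& g : gm) {
      double mA = mass(A, g.first), mB = mass(B, g.first);
      d += plogp(mA - g.second) - plogp(mA) + plogp(mB + g.second) - plogp(mB);
    }
    return d;
  }

  void phys_apply(const std::vector<std::pair<int, double>>& gm, int A, int B) {
    for (const auto& g : gm) {
      uint64_t kA = key(A, g.first);
      auto itA = pm.find(kA);
      double mA = itA == pm.end() ? 0.0 : itA->second;
      double mB = mass(B, g.first);
      physTerm += plogp(mA - g.second) - plogp(mA) + plogp(mB + g.second) - plogp(mB);
      double nA = mA - g.second;
      if (nA <= 1e-15 * mA || nA <= 0) { if (itA != pm.end()) pm.erase(itA); }
      else itA->second = nA;
      pm[key(B, g.first)] = mB + g.second;
    }
  }
};

// one sweep of local moves; returns number of moves made
static int local_move_pass(const FlowNet& net, MoveState& st, Rng& rng) {
  int n = net.n;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  rng.shuffle(order);

  std::vector<double> kflow(st.q.size() + 8, 0.0);
  std::vector<int> stamp(st.q.size() + 8, -1);
  std::vector<int> touched;

  int n_moves = 0;
  for (int idx = 0; idx < n; ++idx) {
    int a = order[idx];
    int A = st.mod[a];
    touched.clear();
    for (int k = net.off[a]; k < net.off[a + 1]; ++k) {
      int m = st.mod[net.nbr[k]];
      if ((size_t)m >= stamp.size()) { stamp.resize(m + 8, -1); kflow.resize(m + 8, 0.0); }
      if (stamp[m] != a) { stamp[m] = a; kflow[m] = 0.0; touched.push_back(m); }
      kflow[m] += net.wt[k];
    }
    double kA = ((size_t)A < stamp.size() && stamp[A] == a) ? kflow[A] : 0.0;

    double qA = st.q[A], psA = st.ps[A];
    double qA2 = qA - net.deg[a] + 2.0 * kA;
    double psA2 = psA - net.p[a];
    double baseA = st.mod_term(qA2, psA2, st.osize[A] - net.nsize[a])
      - st.mod_term(qA, psA, st.osize[A]);

    double bestDelta = -1e-15;
    int bestB = -1;
    double exitC = net.exitC;

    auto consider = [&](int B, double kB) {
      if (B == A) return;
      double qB = st.q[B], psB = st.ps[B];
      double qB2 = qB + net.deg[a] - 2.0 * kB;
      double psB2 = psB + net.p[a];
      double sumQ2 = st.sumQ + 2.0 * (kA - kB);
      double d = (plogp(sumQ2 + exitC) - plogp(st.sumQ + exitC))
        + baseA
        + st.mod_term(qB2, psB2, st.osize[B] + net.nsize[a])
        - st.mod_term(qB, psB, st.osize[B])
        - st.phys_delta(net.npm[a], A, B);
      if (d < bestDelta) { bestDelta = d; bestB = B; }
    };

    for (int m : touched) consider(m, kflow[m]);
    if (st.msize[A] > 1) {
      // splitting off into a fresh module
      int B;
      if (!st.freelist.empty()) B = st.freelist.back();
      else {
        B = (int)st.q.size();
        st.q.push_back(0.0); st.ps.push_back(0.0); st.msize.push_back(0);
        st.osize.push_back(0);
        st.freelist.push_back(B);
      }
      consider(B, 0.0);
    }

    if (bestB >= 0) {
      double kB = ((size_t)bestB < stamp.size() && stamp[bestB] == a) ? kflow[bestB] : 0.0;
      st.phys_apply(net.npm[a], A, bestB);
      st.q[A] = qA2; st.ps[A] = psA2; st.msize[A]--;
      st.osize[A] -= net.nsize[a];
      st.osize[bestB] += net.nsize[a];
      st.q[bestB] = st.q[bestB] + net.deg[a] - 2.0 * kB;
      st.ps[bestB] += net.p[a];
      if (st.msize[bestB] == 0) {
        for (size_t f = 0; f < st.freelist.size(); ++f)
          if (st.freelist[f] == bestB) { st.freelist.erase(st.freelist.begin() + f); break; }
      }
      st.msize[bestB]++;
      st.sumQ += 2.0 * (kA - kB);
      if (st.msize[A] == 0) { st.q[A] = 0; st.ps[A] = 0; st.freelist.push_back(A); }
      st.mod[a] = bestB;
      ++n_moves;
    }
  }
  return n_moves;
}

static void compact_modules(std::vector<int>& mod, int& n_modules) {
  std::unordered_map<int, int> remap;
  int next = 0;
  for (size_t i = 0; i < mod.size(); ++i) {
    auto it = remap.find(mod[i]);
    if (it == remap.end()) { remap[mod[i]] = next; mod[i] = next; ++next; }
    else mod[i] = it->second;
  }
  n_modules = next;
}

static FlowNet aggregate(const FlowNet& net, const std::vector<int>& mod, int n_modules) {
  FlowNet agg;
  agg.n = n_modules;
  agg.exitC = net.exitC;
  agg.p.assign(n_modules, 0.0);
  agg.e.assign(n_modules, 0.0);
  agg.npm.assign(n_modules, {});
  agg.nsize.assign(n_modules, 0);
  std::unordered_map<uint64_t, double> masses;
  uint64_t P = 0;
  for (int i = 0; i < net.n; ++i)
    for (const auto& gm : net.npm[i]) P = std::max(P, (uint64_t)gm.first + 1);
  for (int i = 0; i < net.n; ++i) {
    agg.p[mod[i]] += net.p[i];
    agg.e[mod[i]] += net.e[i];
    agg.nsize[mod[i]] += net.nsize[i];
    for (const auto& gm : net.npm[i])
      masses[(uint64_t)mod[i] * P + (uint64_t)gm.first] += gm.second;
  }
  for (const auto& kv : masses)
    agg.npm[(int)(kv.first / P)].push_back({(int)(kv.first % P), kv.second});
  for (auto& v : agg.npm)
    std::sort(v.begin(), v.end());
  std::map<std::pair<int, int>, double> acc;
  for (size_t l = 0; l < net.eu.size(); ++l) {
    int a = mod[net.eu[l]], b = mod[net.ev[l]];
    if (a == b) continue;
    if (a > b) std::swap(a, b);
    acc[{a, b}] += net.phi[l];
  }
  for (auto& kv : acc) {
    agg.eu.push_back(kv.first.first);
    agg.ev.push_back(kv.first.second);
    agg.phi.push_back(kv.second);
  }
  agg.build_csr();
  return agg;
}

static uint64_t phys_stride(const FlowNet& net) {
  uint64_t P = 1;
  for (int i = 0; i < net.n; ++i)
    for (const auto& gm : net.npm[i]) P = std::max(P, (uint64_t)gm.first + 1);
  return P;
}

// module-aggregated "enter-flow" network used to propose super-module
// levels: node flow is the module's boundary (enter/exit) rate, edges are
// inter-module flows; clustering it with transparent singletons scores the
// index-codebook gain of a candidate level
static FlowNet super_net(const FlowNet& net, const std::vector<int>& mod, int n_modules) {
  FlowNet agg = aggregate(net, mod, n_modules);
  for (int i = 0; i < agg.n; ++i) {
    agg.p[i] = agg.deg[i];
    agg.npm[i].clear();
    agg.npm[i].push_back({i, agg.p[i]});
    agg.nsize[i] = 1;
  }
  return agg;
}

// deterministic greedy agglomeration by maximum inter-group flow; returns
// one grouping per requested group count K (flow-cohesive segment
// candidates: the weakest cuts survive the longest)
static std::vector<std::pair<int, std::vector<int>>> dendro_candidates(
    const FlowNet& agg, int kmin, int kmax) {
  int n = agg.n;
  std::vector<int> grp(n);
  for (int i = 0; i < n; ++i) grp[i] = i;
  std::map<std::pair<int, int>, double> flow;
  for (size_t l = 0; l < agg.eu.size(); ++l) {
    int a = agg.eu[l], b = agg.ev[l];
    if (a > b) std::swap(a, b);
    flow[{a, b}] += agg.phi[l];
  }
  std::vector<std::pair<int, std::vector<int>>> out;
  int ngroups = n;
  auto snapshot = [&]() {
    std::vector<int> g = grp;
    int nn;
    compact_modules(g, nn);
    out.push_back({nn, g});
  };
  if (ngroups >= kmin && ngroups <= kmax) snapshot();
  while (ngroups > std::max(2, kmin) && !flow.empty()) {
    // merge the pair with the largest flow (ties: smaller ids)
    auto bestIt = flow.begin();
    for (auto it = flow.begin(); it != flow.end(); ++it)
      if (it->second > bestIt->second + 1e-18) bestIt = it;
    int a = bestIt->first.first, b = bestIt->first.second;
    for (int i = 0; i < n; ++i) if (grp[i] == b) grp[i] = a;
    // rebuild pair flows touching b onto a
    std::map<std::pair<int, int>, double> nf;
    for (auto& kv : flow) {
      int x = kv.first.first, y = kv.first.second;
      if (x == b) x = a;
      if (y == b) y = a;
      if (x == y) continue;
      if (x > y) std::swap(x, y);
      nf[{x, y}] += kv.second;
    }
    flow.swap(nf);
    --ngroups;
    if (ngroups >= kmin && ngroups <= kmax) snapshot();
  }
  return out;
}


// full search on one FlowNet: Louvain levels + fine-tuning outer loop.
// Half of the trials start from a random coarse partition instead of
// singletons: on chain-like module graphs, pairwise merges from singletons
// are uphill away from the chain ends, and only a coarse start lets the
// local moves reach segment-style optima.
static double search_net(const FlowNet& net, Rng& rng, std::vector<int>& out_mod,
                         bool transparent = false) {
  int n = net.n;
  uint64_t P = phys_stride(net);
  std::vector<int> assign(n);
  int n_modules = n;
  if (n > 2 && !net.eu.empty() && rng.below(2) == 1) {
    // random edge contractions produce flow-connected seed groups
    int target = 2 + rng.below(std::max(2, n / 2));
    UnionFind uf(n);
    int groups = n;
    int attempts = 8 * n;
    while (groups > target && attempts-- > 0) {
      int l = rng.below((int)net.eu.size());
      int a = uf.find(net.eu[l]), b = uf.find(net.ev[l]);
      if (a != b) { uf.unite(a, b); --groups; }
    }
    for (int i = 0; i < n; ++i) assign[i] = uf.find(i);
    compact_modules(assign, n_modules);
  } else {
    for (int i = 0; i < n; ++i) assign[i] = i;
  }

  MoveState st;
  st.transparent_singletons = transparent;
  double bestJ = 1e300;

  for (int outer = 0; outer < 50; ++outer) {
    // phase 1: local moves at the original-node granularity
    st.init_from(net, assign, n_modules, P);
    for (int pass = 0; pass < 200; ++pass)
      if (local_move_pass(net, st, rng) == 0) break;
    assign = st.mod;
    compact_modules(assign, n_modules);

    // phase 2: Louvain aggregation ladder starting from the current partition
    FlowNet cur = aggregate(net, assign, n_modules);
    std::vector<int> super(n_modules);
    for (int i = 0; i < n_modules; ++i) super[i] = i;
    while (cur.n > 1) {
      std::vector<int> sassign(cur.n);
      for (int i = 0; i < cur.n; ++i) sassign[i] = i;
      MoveState sst;
      sst.transparent_singletons = transparent;
      sst.init_from(cur, sassign, cur.n, P);
      for (int pass = 0; pass < 200; ++pass)
        if (local_move_pass(cur, sst, rng) == 0) break;
      sassign = sst.mod;
      int nm;
      compact_modules(sassign, nm);
      if (nm == cur.n) break;
      for (int i = 0; i < n_modules; ++i) super[i] = sassign[super[i]];
      cur = aggregate(cur, sassign, nm);
    }
    for (int i = 0; i < n; ++i) assign[i] = super[assign[i]];
    compact_modules(assign, n_modules);

    st.init_from(net, assign, n_modules, P);
    double J = st.objective(net.exitC);
    if (J < bestJ - 1e-12) bestJ = J;
    else break;
  }
  out_mod = assign;
  return bestJ;
}

// leaf codebook value of a node set treated as one module:
// plogp(q + ps) - sum_phys plogp(merged mass)   (the -plogp(q) exit entry
// lives in the parent index codebook in the J bookkeeping used here)
static double leaf_value(const FlowNet& net, uint64_t P) {
  double ps = 0.0, qm = net.exitC;  // exitC equals the module's boundary flow
  std::unordered_map<uint64_t, double> masses;
  for (int i = 0; i < net.n; ++i) {
    ps += net.p[i];
    for (const auto& gm : net.npm[i]) masses[(uint64_t)gm.first] += gm.second;
  }
  double t = plogp(qm + ps);
  for (const auto& kv : masses) t -= plogp(kv.second);
  return t;
}

struct TreeBuilder {
  const FlowNet* base;
  std::vector<std::vector<int>> paths;  // per node
  int sub_trials;
  uint64_t seed_counter;
  int max_depth;
  uint64_t P;

  void refine(const std::vector<int>& members, double q_mod,
              const std::vector<int>& prefix, int depth) {
    for (int m : members) paths[m] = prefix;
    if ((int)members.size() < 2 || depth >= max_depth) return;

    FlowNet sub;
    sub.n = (int)members.size();
    std::unordered_map<int, int> idx;
    idx.reserve(members.size() * 2);
    for (int i = 0; i < sub.n; ++i) idx[members[i]] = i;
    sub.p.resize(sub.n);
    sub.e.resize(sub.n);
    sub.npm.resize(sub.n);
    sub.nsize.assign(sub.n, 1);
    for (int i = 0; i < sub.n; ++i) {
      sub.p[i] = base->p[members[i]];
      sub.e[i] = base->deg[members[i]];
      sub.npm[i] = base->npm[members[i]];
    }
    for (int i = 0; i < sub.n; ++i) {
      int u = members[i];
      for (int k = base->off[u]; k < base->off[u + 1]; ++k) {
        auto it = idx.find(base->nbr[k]);
        if (it == idx.end()) continue;
        int j = it->second;
        sub.e[i] -= base->wt[k];
        if (i < j) { sub.eu.push_back(i); sub.ev.push_back(j); sub.phi.push_back(base->wt[k]); }
      }
    }
    sub.exitC = q_mod;
    sub.build_csr();

    double bestJ = 1e300;
    std::vector<int> best_mod;
    for (int t = 0; t < sub_trials; ++t) {
      Rng rng(seed_counter++);
      std::vector<int> mod;
      double J = search_net(sub, rng, mod);
      if (J < bestJ - 1e-12) { bestJ = J; best_mod = mod; }
    }
    int nm = 0;
    if (!best_mod.empty()) compact_modules(best_mod, nm);
    if (nm < 2 || bestJ >= leaf_value(sub, P) - 1e-12) return;

    // children ordered by aggregate flow, descending
    std::vector<double> cps(nm, 0.0), cq(nm, 0.0);
    std::vector<std::vector<int>> cmembers(nm);
    for (int i = 0; i < sub.n; ++i) {
      cps[best_mod[i]] += sub.p[i];
      cq[best_mod[i]] += sub.deg[i];
      cmembers[best_mod[i]].push_back(members[i]);
    }
    for (size_t l = 0; l < sub.eu.size(); ++l)
      if (best_mod[sub.eu[l]] == best_mod[sub.ev[l]]) cq[best_mod[sub.eu[l]]] -= 2.0 * sub.phi[l];
    std::vector<int> ord(nm);
    for (int c = 0; c < nm; ++c) ord[c] = c;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (cps[a] != cps[b]) return cps[a] > cps[b];
      return cmembers[a][0] < cmembers[b][0];
    });
    for (int rank = 0; rank < nm; ++rank) {
      int c = ord[rank];
      std::vector<int> cprefix = prefix;
      cprefix.push_back(rank + 1);
      double qc = cq[c];
      if (qc < 0 && qc > -1e-12) qc = 0;
      refine(cmembers[c], qc, cprefix, depth + 1);
    }
  }
};

// hierarchical codelength from node paths on the full flow graph
static double hier_codelength(const FlowNet& net, const std::vector<std::vector<int>>& paths) {
  auto key_of = [](const std::vector<int>& path, int len) {
    std::string k;
    for (int i = 0; i < len; ++i) { k += std::to_string(path[i]); k += ':'; }
    return k;
  };
  struct ModInfo {
    double q = 0.0, ps = 0.0;
    bool leaf = true;
    std::vector<double> child_q;
    std::unordered_map<int, double> masses;  // merged physical masses (leaves)
  };
  std::map<std::string, ModInfo> mods;

  for (int i = 0; i < net.n; ++i) {
    const std::vector<int>& pa = paths[i];
    for (int d = 1; d <= (int)pa.size(); ++d) {
      ModInfo& mi = mods[key_of(pa, d)];
      mi.ps += net.p[i];
      mi.q += net.e[i];
      if (d < (int)pa.size()) mi.leaf = false;
      else for (const auto& gm : net.npm[i]) mi.masses[gm.first] += gm.second;
    }
  }
  for (size_t l = 0; l < net.eu.size(); ++l) {
    const std::vector<int>& pu = paths[net.eu[l]];
    const std::vector<int>& pv = paths[net.ev[l]];
    int cp = 0;
    while (cp < (int)pu.size() && cp < (int)pv.size() && pu[cp] == pv[cp]) ++cp;
    for (int d = cp + 1; d <= (int)pu.size(); ++d) mods[key_of(pu, d)].q += net.phi[l];
    for (int d = cp + 1; d <= (int)pv.size(); ++d) mods[key_of(pv, d)].q += net.phi[l];
  }
  double L = 0.0;
  std::vector<double> root_child_q;
  for (auto& kv : mods) {
    const std::string& key = kv.first;
    size_t pos = key.rfind(':', key.size() - 2);
    if (pos == std::string::npos) root_child_q.push_back(kv.second.q);
    else mods[key.substr(0, pos + 1)].child_q.push_back(kv.second.q);
  }
  {
    double rate = net.exitC;
    for (double qc : root_child_q) rate += qc;
    double h = plogp(rate);
    for (double qc : root_child_q) h -= plogp(qc);
    h -= plogp(net.exitC);
    L += h;
  }
  for (auto& kv : mods) {
    const ModInfo& mi = kv.second;
    if (mi.leaf) {
      double h = plogp(mi.q + mi.ps) - plogp(mi.q);
      for (const auto& gm : mi.masses) h -= plogp(gm.second);
      L += h;
    } else {
      double rate = mi.q;
      for (double qc : mi.child_q) rate += qc;
      double h = plogp(rate);
      for (double qc : mi.child_q) h -= plogp(qc);
      h -= plogp(mi.q);
      L += h;
    }
  }
  return L;
}

static FlowNet base_net_from_r(int n_nodes, NumericVector p,
                               IntegerVector eu, IntegerVector ev, NumericVector phi,
                               IntegerVector phys, bool physical_coding) {
  FlowNet net;
  net.n = n_nodes;
  net.p.assign(p.begin(), p.end());
  net.e.assign(n_nodes, 0.0);
  net.exitC = 0.0;
  net.npm.resize(n_nodes);
  net.nsize.assign(n_nodes, 1);
  for (int i = 0; i < n_nodes; ++i) {
    int g = physical_coding ? phys[i] : i;
    net.npm[i].push_back({g, net.p[i]});
  }
  int E = eu.size();
  net.eu.resize(E); net.ev.resize(E); net.phi.resize(E);
  for (int l = 0; l < E; ++l) { net.eu[l] = eu[l] - 1; net.ev[l] = ev[l] - 1; net.phi[l] = phi[l]; }
  net.build_csr();
  return net;
}

// [[Rcpp::export]]
List infomap_cpp(int n_nodes, NumericVector p,
                 IntegerVector eu, IntegerVector ev, NumericVector phi,
                 IntegerVector phys, bool physical_coding,
                 int seed, int num_trials, bool multilevel, int sub_trials,
                 double level_margin) {
  FlowNet net = base_net_from_r(n_nodes, p, eu, ev, phi, phys, physical_coding);

  if (n_nodes == 1) {
    IntegerMatrix paths(1, 1);
    paths(0, 0) = 1;
    return List::create(_["paths"] = paths, _["codelength"] = 0.0,
                        _["trial_codelengths"] = NumericVector::create());
  }

  double bestJ = 1e300;
  std::vector<int> best_mod;
  NumericVector trialL(num_trials);
  for (int t = 0; t < num_trials; ++t) {
    Rng rng((uint64_t)(uint32_t)(seed + t));
    std::vector<int> mod;
    double J = search_net(net, rng, mod);
    trialL[t] = J;  // two-level codelength of this trial
    if (J < bestJ - 1e-12) { bestJ = J; best_mod = mod; }
  }
  int n_modules;
  compact_modules(best_mod, n_modules);

  // --- index hierarchy above the two-level modules -------------------------
  // Recursively group the modules of each index node (starting at the root)
  // into super-modules: candidates come from a transparent-singleton search
  // on the enter-flow module graph plus flow-cohesive agglomeration cuts;
  // a grouping is kept only if it lowers the node's exact index cost (the
  // subtree cost decomposes, so local acceptance is exact). Accepted supers
  // are recursed into, so different branches can have different depths.
  std::vector<std::vector<int>> mod_prefix(n_modules);
  std::vector<double> mod_flow(n_modules, 0.0);
  for (int i = 0; i < n_nodes; ++i) mod_flow[best_mod[i]] += net.p[i];
  {
    uint64_t sseed = (uint64_t)(uint32_t)seed * 2654435761ULL + 13ULL;
    // global work budget for the look-ahead recursion: when exhausted,
    // deeper nodes keep their children flat instead of exploring groupings
    long build_budget = 20000;

    // best grouping of the module graph's nodes under the transparent index
    // objective (candidates: search + flow-cohesive agglomeration cuts);
    // empty result means no grouping beats keeping all nodes direct children
    // candidate groupings of a module graph's nodes: best transparent-index
    // search result plus flow-cohesive agglomeration cuts
    auto candidate_groupings = [&](const FlowNet& mg, int trials, int kmax) {
      std::vector<std::vector<int>> cands;
      int n = mg.n;
      if (n < 3) return cands;
      {
        double bestJs = 1e300;
        std::vector<int> smod;
        for (int t = 0; t < std::max(1, trials); ++t) {
          Rng rng(sseed++);
          std::vector<int> m;
          double J = search_net(mg, rng, m, true);
          if (J < bestJs - 1e-12) { bestJs = J; smod = m; }
        }
        if (!smod.empty()) cands.push_back(smod);
      }
      for (auto& kc : dendro_candidates(mg, 2, std::min(n - 1, kmax)))
        cands.push_back(kc.second);
      return cands;
    };

    // module graph restricted to a node subset (enter-flow semantics kept:
    // node flow = module boundary rate; e = flow leaving the subset)
    auto induce = [](const FlowNet& mg, const std::vector<int>& members,
                     double exitC) {
      FlowNet sub;
      sub.n = (int)members.size();
      std::unordered_map<int, int> idx;
      for (int i = 0; i < sub.n; ++i) idx[members[i]] = i;
      sub.p.resize(sub.n);
      sub.e.resize(sub.n);
      sub.npm.resize(sub.n);
      sub.nsize.assign(sub.n, 1);
      for (int i = 0; i < sub.n; ++i) {
        int u = members[i];
        sub.p[i] = mg.p[u];
        sub.e[i] = mg.deg[u];
        sub.npm[i].push_back({i, sub.p[i]});
      }
      for (size_t l = 0; l < mg.eu.size(); ++l) {
        auto iu = idx.find(mg.eu[l]), iv = idx.find(mg.ev[l]);
        if (iu == idx.end() || iv == idx.end()) continue;
        sub.e[iu->second] -= mg.phi[l];
        sub.e[iv->second] -= mg.phi[l];
        sub.eu.push_back(iu->second);
        sub.ev.push_back(iv->second);
        sub.phi.push_back(mg.phi[l]);
      }
      sub.exitC = exitC;
      sub.build_csr();
      return sub;
    };

    // index-tree builder with exact look-ahead: a candidate grouping of this
    // node's modules is scored by the node codebook it implies PLUS the
    // recursively optimized index cost inside each group, so a super-module
    // that only pays off once its interior is nested is still found. Returns
    // the subtree's total index cost and the ranked path of every module
    // (relative to this node); leaf-module codebooks are constant and
    // excluded throughout.
    struct IdxRes {
      double cost = 0.0;
      std::vector<std::pair<int, std::vector<int>>> paths;  // (module id, rel path)
    };
    std::function<IdxRes(const FlowNet&, const std::vector<int>&, int)> build =
      [&](const FlowNet& mg, const std::vector<int>& orig, int depth) -> IdxRes {
        int n = mg.n;
        --build_budget;
        // node codebook cost for a grouping (entries: group boundary flows
        // and transparent singleton module flows, plus this node's exit)
        auto node_cost = [&](const std::vector<double>& entries) {
          double rate = mg.exitC;
          double c = 0.0;
          for (double q : entries) { rate += q; c -= plogp(q); }
          c += plogp(rate) - plogp(mg.exitC);
          return c;
        };

        // baseline: every module a direct child. Among candidates whose
        // exact look-ahead cost is within `level_margin` bits of the
        // minimum, the FINEST grouping (most direct children) is kept:
        // a hierarchy level must pay for itself, which stops near-free
        // "shell" supers on flat codelength landscapes.
        std::vector<double> flat_entries(n);
        for (int i = 0; i < n; ++i) flat_entries[i] = mg.deg[i];
        double flatCost = node_cost(flat_entries);
        double bestCost = flatCost;
        std::vector<int> bestGrouping;  // empty = flat
        std::vector<IdxRes> bestSub;
        std::vector<std::vector<int>> bestMembers;
        int bestNs = n;

        if (multilevel && n >= 3 && depth < 8 && build_budget > 0) {
          int trials = std::max(2, sub_trials >> depth);
          struct Cand {
            double cost;
            int ns;
            std::vector<int> grouping;
            std::vector<IdxRes> sub;
            std::vector<std::vector<int>> members;
          };
          std::vector<Cand> scored;
          int kmax = 10;
          for (auto smod : candidate_groupings(mg, trials, kmax)) {
            int ns;
            compact_modules(smod, ns);
            if (ns <= 1 || ns >= n) continue;
            std::vector<std::vector<int>> gmembers(ns);
            std::vector<double> gq(ns, 0.0);
            for (int i = 0; i < n; ++i) {
              gmembers[smod[i]].push_back(i);
              gq[smod[i]] += mg.deg[i];
            }
            for (size_t l = 0; l < mg.eu.size(); ++l)
              if (smod[mg.eu[l]] == smod[mg.ev[l]])
                gq[smod[mg.eu[l]]] -= 2.0 * mg.phi[l];
            std::vector<double> entries;
            std::vector<IdxRes> subres(ns);
            double cost = 0.0;
            for (int g = 0; g < ns; ++g) {
              double qg = gq[g] < 0 ? 0 : gq[g];
              entries.push_back(gmembers[g].size() == 1 ? mg.deg[gmembers[g][0]] : qg);
              if (gmembers[g].size() >= 2) {
                std::vector<int> sorig(gmembers[g].size());
                for (size_t i = 0; i < gmembers[g].size(); ++i)
                  sorig[i] = orig[gmembers[g][i]];
                subres[g] = build(induce(mg, gmembers[g], qg), sorig, depth + 1);
                cost += subres[g].cost;
              }
            }
            cost += node_cost(entries);
            scored.push_back({cost, ns, std::move(smod), std::move(subres),
                              std::move(gmembers)});
          }
          double minCost = flatCost;
          for (auto& c : scored) minCost = std::min(minCost, c.cost);
          if (flatCost > minCost + level_margin) {
            // flat loses; keep the finest candidate within the margin
            for (auto& c : scored) {
              if (c.cost > minCost + level_margin) continue;
              if (bestGrouping.empty() || c.ns > bestNs ||
                  (c.ns == bestNs && c.cost < bestCost - 1e-12)) {
                bestCost = c.cost;
                bestNs = c.ns;
                bestGrouping = c.grouping;
                bestSub = std::move(c.sub);
                bestMembers = std::move(c.members);
              }
            }
          }
        }

        IdxRes res;
        res.cost = bestCost;
        if (bestGrouping.empty()) {
          // rank modules by flow
          std::vector<int> ord(n);
          for (int i = 0; i < n; ++i) ord[i] = i;
          std::sort(ord.begin(), ord.end(), [&](int a, int b) {
            double fa = mod_flow[orig[a]], fb = mod_flow[orig[b]];
            if (fa != fb) return fa > fb;
            return orig[a] < orig[b];
          });
          for (int rank = 0; rank < n; ++rank)
            res.paths.push_back({orig[ord[rank]], {rank + 1}});
          return res;
        }
        int ns = (int)bestMembers.size();
        std::vector<double> gflow(ns, 0.0);
        for (int g = 0; g < ns; ++g)
          for (int i : bestMembers[g]) gflow[g] += mod_flow[orig[i]];
        std::vector<int> ord(ns);
        for (int g = 0; g < ns; ++g) ord[g] = g;
        std::sort(ord.begin(), ord.end(), [&](int a, int b) {
          if (gflow[a] != gflow[b]) return gflow[a] > gflow[b];
          return orig[bestMembers[a][0]] < orig[bestMembers[b][0]];
        });
        for (int rank = 0; rank < ns; ++rank) {
          int g = ord[rank];
          if (bestMembers[g].size() == 1) {
            res.paths.push_back({orig[bestMembers[g][0]], {rank + 1}});
          } else {
            for (auto& pr : bestSub[g].paths) {
              std::vector<int> pa;
              pa.push_back(rank + 1);
              pa.insert(pa.end(), pr.second.begin(), pr.second.end());
              res.paths.push_back({pr.first, pa});
            }
          }
        }
        return res;
      };

    FlowNet root_mg = super_net(net, best_mod, n_modules);
    std::vector<int> all_orig(n_modules);
    for (int m = 0; m < n_modules; ++m) all_orig[m] = m;
    IdxRes root_res = build(root_mg, all_orig, 0);
    for (auto& pr : root_res.paths) mod_prefix[pr.first] = pr.second;
  }


  // boundary flow of each two-level module, for the downward refinement
  MoveState st;
  st.init_from(net, best_mod, n_modules, phys_stride(net));
  std::vector<std::vector<int>> members(n_modules);
  for (int i = 0; i < n_nodes; ++i) members[best_mod[i]].push_back(i);

  TreeBuilder tb;
  tb.base = &net;
  tb.sub_trials = multilevel ? std::max(1, sub_trials) : 0;
  tb.seed_counter = (uint64_t)(uint32_t)seed * 1000003ULL + 7ULL;
  tb.max_depth = 12;
  tb.P = phys_stride(net);
  tb.paths.assign(n_nodes, {});
  for (int m = 0; m < n_modules; ++m) {
    const std::vector<int>& prefix = mod_prefix[m];
    double qm = st.q[m];
    if (qm < 0 && qm > -1e-12) qm = 0;
    if (multilevel) tb.refine(members[m], qm, prefix, (int)prefix.size());
    else for (int i : members[m]) tb.paths[i] = prefix;
  }

  double L = hier_codelength(net, tb.paths);

  int max_depth = 1;
  for (int i = 0; i < n_nodes; ++i) max_depth = std::max(max_depth, (int)tb.paths[i].size());
  IntegerMatrix paths(n_nodes, max_depth);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < max_depth; ++d)
      paths(i, d) = d < (int)tb.paths[i].size() ? tb.paths[i][d] : 0;

  return List::create(_["paths"] = paths, _["codelength"] = L,
                      _["trial_codelengths"] = trialL);
}

// [[Rcpp::export]]
double hier_codelength_cpp(int n_nodes, NumericVector p,
                           IntegerVector eu, IntegerVector ev, NumericVector phi,
                           IntegerVector phys, bool physical_coding,
                           IntegerMatrix paths) {
  FlowNet net = base_net_from_r(n_nodes, p, eu, ev, phi, phys, physical_coding);
  std::vector<std::vector<int>> pv(n_nodes);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < paths.ncol(); ++d)
      if (paths(i, d) > 0) pv[i].push_back(paths(i, d));
  return hier_codelength(net, pv);
}
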