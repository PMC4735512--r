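// Lattice Monte-Carlo core for the strings-and-binders chromatin model.
//
// Geometry: simple cubic lattice, integer coordinates. Chain bonds start at
// unit length; pivot moves (signed-permutation symmetries) preserve bond
// lengths exactly, single-site fallback moves keep squared bond lengths in
// {1, 2}. Self-avoidance is enforced on every proposal.
//
// Binders: each molecule is either free (well-mixed reservoir) or bound to a
// node. A bound molecule carries a fixed number of interaction surfaces
// (default 1); a surface is consumed by a bridge bond or by a cap placed by
// a polymerization-dead (ML) molecule in the capping variant.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <map>
#include <set>
#include <algorithm>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

// ---- coordinate hashing -------------------------------------------------

static inline long long pack_coord(int x, int y, int z) {
  const long long B = 1 << 20;
  return (((long long)(x + B)) << 42) | (((long long)(y + B)) << 21) |
         ((long long)(z + B));
}

typedef std::array<int, 3> Vec3;

static inline long long pack_v(const Vec3& v) {
  return pack_coord(v[0], v[1], v[2]);
}

static inline double dist2(const Vec3& a, const Vec3& b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// ---- octahedral symmetry group ------------------------------------------

// 48 signed permutation matrices; index 0 is the identity, 1..47 the
// non-identity lattice symmetries used by the pivot algorithm.
static int SYM[48][3][3];
static bool sym_ready = false;

static void init_syms() {
  if (sym_ready) return;
  int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                     {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  int idx = 1;
  for (int p = 0; p < 6; ++p) {
    for (int s = 0; s < 8; ++s) {
      int M[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      for (int r = 0; r < 3; ++r) {
        int sign = (s >> r) & 1 ? -1 : 1;
        M[r][perms[p][r]] = sign;
      }
      bool ident = M[0][0] == 1 && M[1][1] == 1 && M[2][2] == 1;
      int tgt = ident ? 0 : idx++;
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c) SYM[tgt][r][c] = M[r][c];
    }
  }
  sym_ready = true;
}

static inline Vec3 apply_sym(int s, const Vec3& v) {
  Vec3 out;
  for (int r = 0; r < 3; ++r)
    out[r] = SYM[s][r][0] * v[0] + SYM[s][r][1] * v[1] + SYM[s][r][2] * v[2];
  return out;
}

static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// ---- polymer moves -------------------------------------------------------

static std::vector<Vec3> coords_from_matrix(const IntegerMatrix& m) {
  std::vector<Vec3> c(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) c[i] = {m(i, 0), m(i, 1), m(i, 2)};
  return c;
}

static IntegerMatrix coords_to_matrix(const std::vector<Vec3>& c) {
  IntegerMatrix m(c.size(), 3);
  for (size_t i = 0; i < c.size(); ++i) {
    m(i, 0) = c[i][0];
    m(i, 1) = c[i][1];
    m(i, 2) = c[i][2];
  }
  return m;
}

// Pivot: keep nodes 0..k fixed, rotate arm k+1..n-1 about node k by symmetry
// s. Returns false (invalid) on any coordinate collision.
static bool pivot_move(const std::vector<Vec3>& coords, int k, int s,
                       std::vector<Vec3>& out) {
  init_syms();
  int n = coords.size();
  out = coords;
  std::unordered_set<long long> seen;
  seen.reserve(n * 2);
  for (int i = 0; i <= k; ++i) seen.insert(pack_v(coords[i]));
  bool ok = true;
  for (int i = k + 1; i < n; ++i) {
    Vec3 d = {coords[i][0] - coords[k][0], coords[i][1] - coords[k][1],
              coords[i][2] - coords[k][2]};
    Vec3 r = apply_sym(s, d);
    Vec3 nw = {coords[k][0] + r[0], coords[k][1] + r[1], coords[k][2] + r[2]};
    if (!seen.insert(pack_v(nw)).second) ok = false;
    out[i] = nw;
  }
  return ok;
}

static const int UNIT[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                               {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};

// Single-site displacement keeping squared bond lengths to chain neighbours
// in {1, 2} and avoiding collisions.
static bool local_move(const std::vector<Vec3>& coords, int u, int dir,
                       std::vector<Vec3>& out) {
  int n = coords.size();
  Vec3 nw = {coords[u][0] + UNIT[dir][0], coords[u][1] + UNIT[dir][1],
             coords[u][2] + UNIT[dir][2]};
  out = coords;
  out[u] = nw;
  bool ok = true;
  if (u > 0) {
    double d2 = dist2(nw, coords[u - 1]);
    if (d2 != 1.0 && d2 != 2.0) ok = false;
  }
  if (u < n - 1) {
    double d2 = dist2(nw, coords[u + 1]);
    if (d2 != 1.0 && d2 != 2.0) ok = false;
  }
  long long key = pack_v(nw);
  for (int i = 0; i < n; ++i)
    if (i != u && pack_v(coords[i]) == key) ok = false;
  return ok;
}

// [[Rcpp::export]]
List cpp_propose_pivot(IntegerMatrix coords, int pivot_index, int sym_index) {
  init_syms();
  std::vector<Vec3> c = coords_from_matrix(coords), out;
  bool ok = pivot_move(c, pivot_index, sym_index, out);
  return List::create(_["coords"] = coords_to_matrix(out),
                      _["valid"] = ok);
}

// [[Rcpp::export]]
List cpp_propose_local(IntegerMatrix coords, int node_index, int dir_index) {
  std::vector<Vec3> c = coords_from_matrix(coords), out;
  bool ok = local_move(c, node_index, dir_index, out);
  return List::create(_["coords"] = coords_to_matrix(out),
                      _["valid"] = ok);
}

// Straight rod followed by a pivot burn-in of `n_accepts` accepted moves;
// the result is a valid self-avoiding configuration.
// [[Rcpp::export]]
IntegerMatrix cpp_init_polymer(int n_nodes, int n_accepts) {
  init_syms();
  std::vector<Vec3> c(n_nodes);
  for (int i = 0; i < n_nodes; ++i) c[i] = {i, 0, 0};
  if (n_nodes >= 3) {
    int accepted = 0;
    long long tries = 0, max_tries = (long long)n_accepts * 1000 + 1000;
    std::vector<Vec3> prop;
    while (accepted < n_accepts && tries < max_tries) {
      ++tries;
      int k = rand_int(n_nodes - 1);       // pivot node 0..n-2
      int s = 1 + rand_int(47);            // non-identity symmetry
      if (pivot_move(c, k, s, prop)) {
        c = prop;
        ++accepted;
      }
    }
  }
  return coords_to_matrix(c);
}

// ---- binder state --------------------------------------------------------

struct Params {
  double k_a_endog, k_d_endog, k_a_exog, k_d_exog;
  double k_join, k_break, E_bond, neighbor_radius2;
  int N_max;        // -1 = unlimited
  int n_surfaces;   // interaction surfaces per molecule
  bool capping;
};

static Params params_from_list(List p) {
  Params q;
  q.k_a_endog = as<double>(p["k_a_endog"]);
  q.k_d_endog = as<double>(p["k_d_endog"]);
  q.k_a_exog = as<double>(p["k_a_exog"]);
  q.k_d_exog = as<double>(p["k_d_exog"]);
  q.k_join = as<double>(p["k_join"]);
  q.k_break = as<double>(p["k_break"]);
  q.E_bond = as<double>(p["E_bond"]);
  q.neighbor_radius2 = as<double>(p["neighbor_radius2"]);
  q.N_max = as<int>(p["N_max"]);
  q.n_surfaces = as<int>(p["n_surfaces"]);
  q.capping = as<bool>(p["capping"]);
  return q;
}

struct SimState {
  std::vector<Vec3> coords;
  std::vector<double> affinity;
  std::vector<int> species;  // 1 endog Ph, 2 exog Ph, 3 exog Ph-ML
  std::vector<int> node;     // -1 = free
  std::vector<int> nbonds;   // bridge bonds held
  std::vector<int> capped;   // surfaces lost to capping
  std::vector<std::pair<int, int>> bonds;
  int n_capped_total;
};

static inline int surf_free(const SimState& st, const Params& p, int b) {
  // the ML polymerization interface is what bridging requires, so Ph-ML
  // molecules present no bridging surface in either mutant mechanism
  if (st.species[b] == 3) return 0;
  int s = p.n_surfaces - st.nbonds[b] - st.capped[b];
  return s > 0 ? s : 0;
}

static inline bool is_ph(int species) { return species != 3; }

static inline double ka_of(const Params& p, int species) {
  return species == 1 ? p.k_a_endog : p.k_a_exog;
}
static inline double kd_of(const Params& p, int species) {
  return species == 1 ? p.k_d_endog : p.k_d_exog;
}

static SimState state_from_list(List s) {
  SimState st;
  IntegerMatrix cm = s["coords"];
  st.coords = coords_from_matrix(cm);
  st.affinity = as<std::vector<double>>(s["affinity"]);
  st.species = as<std::vector<int>>(s["species"]);
  IntegerVector nd = s["node"];
  st.node.resize(nd.size());
  for (int i = 0; i < nd.size(); ++i) st.node[i] = nd[i] - 1;  // R 0 -> -1
  st.nbonds = as<std::vector<int>>(s["nbonds"]);
  st.capped = as<std::vector<int>>(s["capped"]);
  IntegerMatrix bm = s["bonds"];
  for (int i = 0; i < bm.nrow(); ++i)
    st.bonds.push_back({bm(i, 0) - 1, bm(i, 1) - 1});
  st.n_capped_total = as<int>(s["n_capped"]);
  return st;
}

static List state_to_list(const SimState& st) {
  IntegerVector nd(st.node.size());
  for (size_t i = 0; i < st.node.size(); ++i) nd[i] = st.node[i] + 1;
  IntegerMatrix bm(st.bonds.size(), 2);
  for (size_t i = 0; i < st.bonds.size(); ++i) {
    bm(i, 0) = st.bonds[i].first + 1;
    bm(i, 1) = st.bonds[i].second + 1;
  }
  return List::create(
      _["coords"] = coords_to_matrix(st.coords),
      _["affinity"] = NumericVector(st.affinity.begin(), st.affinity.end()),
      _["species"] = IntegerVector(st.species.begin(), st.species.end()),
      _["node"] = nd,
      _["nbonds"] = IntegerVector(st.nbonds.begin(), st.nbonds.end()),
      _["capped"] = IntegerVector(st.capped.begin(), st.capped.end()),
      _["bonds"] = bm, _["n_capped"] = st.n_capped_total);
}

// ---- union-find over bound binders --------------------------------------

struct UF {
  std::vector<int> parent;
  UF(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) { parent[find(a)] = find(b); }
};

// Clusters = maximal sets of bound binders connected by node co-occupancy
// or bridge bonds.
static void build_clusters(const SimState& st, UF& uf) {
  int nb = st.species.size();
  std::unordered_map<int, int> first_at_node;
  for (int b = 0; b < nb; ++b) {
    if (st.node[b] < 0) continue;
    auto it = first_at_node.find(st.node[b]);
    if (it == first_at_node.end())
      first_at_node[st.node[b]] = b;
    else
      uf.unite(b, it->second);
  }
  for (auto& bd : st.bonds) uf.unite(bd.first, bd.second);
}

// [[Rcpp::export]]
IntegerVector cpp_cluster_census(List state) {
  SimState st = state_from_list(state);
  int nb = st.species.size();
  UF uf(nb);
  build_clusters(st, uf);
  IntegerVector lab(nb, NA_INTEGER);
  std::unordered_map<int, int> relab;
  int next = 1;
  for (int b = 0; b < nb; ++b) {
    if (st.node[b] < 0) continue;
    int r = uf.find(b);
    auto it = relab.find(r);
    if (it == relab.end()) {
      relab[r] = next;
      lab[b] = next++;
    } else
      lab[b] = it->second;
  }
  return lab;
}

// ---- binding (mass-action association / dissociation) --------------------

static void remove_bonds_of(SimState& st, int b) {
  std::vector<std::pair<int, int>> keep;
  keep.reserve(st.bonds.size());
  for (auto& bd : st.bonds) {
    if (bd.first == b || bd.second == b) {
      st.nbonds[bd.first]--;
      st.nbonds[bd.second]--;
    } else
      keep.push_back(bd);
  }
  st.bonds.swap(keep);
}

static void binding_phase(SimState& st, const Params& p) {
  int nb = st.species.size();
  int n_nodes = st.coords.size();

  // dissociation first: polymerization stabilizes resident molecules, so
  // the per-molecule unbinding probability is k_d divided by the node's
  // occupancy; a molecule returning to solution loses its bridge bonds
  // and its cap state resets
  {
    std::vector<int> occ0(n_nodes, 0);
    for (int b = 0; b < nb; ++b)
      if (st.node[b] >= 0) occ0[st.node[b]]++;
    for (int b = 0; b < nb; ++b) {
      if (st.node[b] < 0) continue;
      if (unif_rand() < kd_of(p, st.species[b]) / occ0[st.node[b]]) {
        remove_bonds_of(st, b);
        st.node[b] = -1;
        st.capped[b] = 0;
      }
    }
  }

  // cluster bookkeeping for the capping gate; per-node count of uncapped
  // Ph (each presents one surface that recruits further molecules)
  UF uf(nb);
  std::vector<int> occ(n_nodes, 0);
  std::vector<int> surf_at(n_nodes, 0);       // uncapped Ph per node
  std::vector<int> node_member(n_nodes, -1);  // one resident per node
  if (p.capping) build_clusters(st, uf);
  std::unordered_map<int, int> gate_of_root;
  for (int b = 0; b < nb; ++b) {
    if (st.node[b] < 0) continue;
    occ[st.node[b]]++;
    node_member[st.node[b]] = b;
    if (is_ph(st.species[b]) && st.capped[b] == 0) {
      surf_at[st.node[b]]++;
      if (p.capping) gate_of_root[uf.find(b)]++;
    }
  }

  // free pools
  int free_by_sp[4] = {0, 0, 0, 0};
  for (int b = 0; b < nb; ++b)
    if (st.node[b] < 0) free_by_sp[st.species[b]]++;

  // Molecule-centric mass action: each free molecule binds this step with
  // hazard min(1, k_a * sum_v W_v) and chooses a node in proportion to
  // W_v = A_v * (1 + occ_v); every bound molecule adds local avidity, so
  // spreading is cooperative. Weights are frozen at the start of the step
  // (tau-leap); occupancy caps and the capping gate are checked live, a
  // blocked draw leaves the molecule free.
  std::vector<double> cumw(n_nodes);
  double sw = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    sw += st.affinity[v] * (1.0 + occ[v]);
    cumw[v] = sw;
  }
  if (sw <= 0) return;

  for (int b = 0; b < nb; ++b) {
    if (st.node[b] >= 0) continue;
    int s = st.species[b];
    double hazard = ka_of(p, s) * sw;
    if (hazard > 1.0) hazard = 1.0;
    if (unif_rand() >= hazard) continue;
    double r = unif_rand() * sw;
    int v = std::lower_bound(cumw.begin(), cumw.end(), r) - cumw.begin();
    if (v >= n_nodes) v = n_nodes - 1;
    if (p.N_max >= 0 && occ[v] >= p.N_max) continue;  // saturated node
    bool joining = occ[v] > 0;
    int root = -1;
    if (p.capping) {
      if (joining) {
        root = uf.find(node_member[v]);
        if (gate_of_root[root] == 0) continue;  // fully capped cluster
        uf.unite(b, node_member[v]);
        root = uf.find(b);
      } else
        root = uf.find(b);
    }
    st.node[b] = v;
    st.nbonds[b] = 0;
    st.capped[b] = 0;
    occ[v]++;
    node_member[v] = b;
    free_by_sp[s]--;
    if (is_ph(s)) surf_at[v]++;
    if (p.capping) {
      if (is_ph(s)) gate_of_root[root]++;
      if (s == 3 && joining) {
        // Ph-ML joining a cluster caps one uncapped resident Ph,
        // chosen uniformly
        std::vector<int> cands;
        for (int i = 0; i < nb; ++i)
          if (i != b && st.node[i] >= 0 && is_ph(st.species[i]) &&
              st.capped[i] == 0 && uf.find(i) == root)
            cands.push_back(i);
        if (!cands.empty()) {
          int victim = cands[rand_int(cands.size())];
          st.capped[victim] = 1;
          st.n_capped_total++;
          gate_of_root[root]--;
          surf_at[st.node[victim]]--;
        }
      }
    }
  }
}

// ---- bridging ------------------------------------------------------------

static inline long long bond_key(int i, int j, int nb) {
  if (i > j) std::swap(i, j);
  return (long long)i * nb + j;
}

static void bridging_phase(SimState& st, const Params& p) {
  int nb = st.species.size();
  int n_nodes = st.coords.size();

  // break existing bonds
  if (!st.bonds.empty()) {
    std::vector<std::pair<int, int>> keep;
    keep.reserve(st.bonds.size());
    for (auto& bd : st.bonds) {
      if (unif_rand() < p.k_break) {
        st.nbonds[bd.first]--;
        st.nbonds[bd.second]--;
      } else
        keep.push_back(bd);
    }
    st.bonds.swap(keep);
  }

  std::unordered_set<long long> have;
  for (auto& bd : st.bonds) have.insert(bond_key(bd.first, bd.second, nb));

  // members per occupied node
  std::unordered_map<int, std::vector<int>> members;
  for (int b = 0; b < nb; ++b)
    if (st.node[b] >= 0) members[st.node[b]].push_back(b);

  // candidate node pairs within the neighbour radius
  std::vector<std::pair<int, int>> node_pairs;
  if (p.neighbor_radius2 <= 3.0 + 1e-9) {
    std::unordered_map<long long, int> at;
    for (auto& kv : members) at[pack_v(st.coords[kv.first])] = kv.first;
    for (auto& kv : members) {
      int a = kv.first;
      const Vec3& c = st.coords[a];
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            if (dx * dx + dy * dy + dz * dz > p.neighbor_radius2) continue;
            auto it = at.find(pack_coord(c[0] + dx, c[1] + dy, c[2] + dz));
            if (it != at.end() && it->second > a)
              node_pairs.push_back({a, it->second});
          }
    }
  } else {
    std::vector<int> occ_nodes;
    for (auto& kv : members) occ_nodes.push_back(kv.first);
    for (size_t i = 0; i < occ_nodes.size(); ++i)
      for (size_t j = i + 1; j < occ_nodes.size(); ++j)
        if (dist2(st.coords[occ_nodes[i]], st.coords[occ_nodes[j]]) <=
            p.neighbor_radius2)
          node_pairs.push_back({occ_nodes[i], occ_nodes[j]});
  }

  for (auto& np : node_pairs) {
    for (int i : members[np.first]) {
      if (surf_free(st, p, i) == 0) continue;
      for (int j : members[np.second]) {
        if (surf_free(st, p, i) == 0) break;
        if (surf_free(st, p, j) == 0) continue;
        if (have.count(bond_key(i, j, nb))) continue;
        if (unif_rand() < p.k_join) {
          st.bonds.push_back({std::min(i, j), std::max(i, j)});
          st.nbonds[i]++;
          st.nbonds[j]++;
          have.insert(bond_key(i, j, nb));
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_binding_step(List state, List params) {
  SimState st = state_from_list(state);
  Params p = params_from_list(params);
  binding_phase(st, p);
  return state_to_list(st);
}

// [[Rcpp::export]]
List cpp_bridging_step(List state, List params) {
  SimState st = state_from_list(state);
  Params p = params_from_list(params);
  bridging_phase(st, p);
  return state_to_list(st);
}

// Bridge bonds broken by a coordinate change: a bond breaks when its two
// nodes end up farther apart than the neighbour radius.
// [[Rcpp::export]]
IntegerVector cpp_broken_bonds(IntegerMatrix coords_new, List state,
                               double neighbor_radius2) {
  SimState st = state_from_list(state);
  std::vector<Vec3> nc = coords_from_matrix(coords_new);
  std::vector<int> broken;
  for (size_t k = 0; k < st.bonds.size(); ++k) {
    int vi = st.node[st.bonds[k].first], vj = st.node[st.bonds[k].second];
    if (vi < 0 || vj < 0) continue;
    if (dist2(nc[vi], nc[vj]) > neighbor_radius2) broken.push_back(k + 1);
  }
  return IntegerVector(broken.begin(), broken.end());
}

// ---- full simulation loop ------------------------------------------------

static void polymer_move(SimState& st, const Params& p, int& acc_pivot,
                         int& acc_local) {
  int n = st.coords.size();
  if (n < 2) return;
  std::vector<Vec3> prop;
  bool ok = false;
  bool was_pivot = false;
  if (n >= 3) {
    int k = rand_int(n - 1);
    int s = 1 + rand_int(47);
    ok = pivot_move(st.coords, k, s, prop);
    was_pivot = ok;
  }
  if (!ok) {
    int u = rand_int(n);
    int d = rand_int(6);
    ok = local_move(st.coords, u, d, prop);
  }
  if (!ok) return;

  // Metropolis on bond-breaking moves
  std::vector<int> broken;
  for (size_t k = 0; k < st.bonds.size(); ++k) {
    int vi = st.node[st.bonds[k].first], vj = st.node[st.bonds[k].second];
    if (vi < 0 || vj < 0) continue;
    if (dist2(prop[vi], prop[vj]) > p.neighbor_radius2) broken.push_back(k);
  }
  if (!broken.empty()) {
    double dE = p.E_bond * broken.size();
    if (unif_rand() >= std::exp(-dE)) return;  // rejected
    for (int idx = (int)broken.size() - 1; idx >= 0; --idx) {
      int k = broken[idx];
      st.nbonds[st.bonds[k].first]--;
      st.nbonds[st.bonds[k].second]--;
      st.bonds.erase(st.bonds.begin() + k);
    }
  }
  st.coords = prop;
  if (was_pivot)
    ++acc_pivot;
  else
    ++acc_local;
}

// One independent simulation run. Snapshots are taken every `snapshot_every`
// steps after the first `burnin_frac` fraction of steps.
// [[Rcpp::export]]
List cpp_run_iteration(int n_nodes, int N_endog, int N_exog, int exog_species,
                       List params, int n_steps, int snapshot_every,
                       double burnin_frac, int init_accepts) {
  Params p = params_from_list(params);
  SimState st;
  {
    IntegerMatrix cm = cpp_init_polymer(n_nodes, init_accepts);
    st.coords = coords_from_matrix(cm);
  }
  st.affinity.resize(n_nodes);
  for (int v = 0; v < n_nodes; ++v) st.affinity[v] = unif_rand();
  int nb = N_endog + N_exog;
  st.species.assign(nb, 1);
  for (int b = N_endog; b < nb; ++b) st.species[b] = exog_species;
  st.node.assign(nb, -1);
  st.nbonds.assign(nb, 0);
  st.capped.assign(nb, 0);
  st.n_capped_total = 0;

  int burn = (int)std::floor(n_steps * burnin_frac);
  int acc_pivot = 0, acc_local = 0;

  std::vector<IntegerVector> snapshots_sizes;
  std::map<std::pair<int, int>, int> contact_count;
  std::vector<bool> ever_occ(n_nodes, false);
  std::vector<double> e2e2, cluster_cf;
  std::vector<int> bound_endog, bound_exog;

  for (int step = 1; step <= n_steps; ++step) {
    polymer_move(st, p, acc_pivot, acc_local);
    binding_phase(st, p);
    bridging_phase(st, p);

    if (step > burn && (step - burn) % snapshot_every == 0) {
      // cluster census
      UF uf(nb);
      build_clusters(st, uf);
      std::unordered_map<int, int> size_of;
      int nbound_en = 0, nbound_ex = 0;
      std::vector<bool> occ_now(n_nodes, false);
      std::vector<int> occ_cnt(n_nodes, 0);
      for (int b = 0; b < nb; ++b) {
        if (st.node[b] < 0) continue;
        size_of[uf.find(b)]++;
        occ_now[st.node[b]] = true;
        occ_cnt[st.node[b]]++;
        if (st.species[b] == 1)
          ++nbound_en;
        else
          ++nbound_ex;
      }
      IntegerVector sizes(size_of.size());
      int si = 0;
      for (auto& kv : size_of) sizes[si++] = kv.second;
      snapshots_sizes.push_back(sizes);
      for (int v = 0; v < n_nodes; ++v)
        if (occ_now[v]) ever_occ[v] = true;
      // node pairs linked by >=1 bridge this snapshot
      std::set<std::pair<int, int>> pairs_now;
      for (auto& bd : st.bonds) {
        int a = st.node[bd.first], b2 = st.node[bd.second];
        if (a == b2) continue;
        pairs_now.insert({std::min(a, b2), std::max(a, b2)});
      }
      for (auto& pr : pairs_now) contact_count[pr]++;
      // contact frequency among cluster sites (nodes holding >= 2
      // molecules): bridged pairs / all pairs of such sites
      long long n_multi = 0;
      for (int v = 0; v < n_nodes; ++v)
        if (occ_cnt[v] >= 2) ++n_multi;
      long long multi_pairs = n_multi * (n_multi - 1) / 2;
      int bonded_multi = 0;
      for (auto& pr : pairs_now)
        if (occ_cnt[pr.first] >= 2 && occ_cnt[pr.second] >= 2)
          ++bonded_multi;
      // undefined when fewer than two cluster sites exist this snapshot
      if (multi_pairs > 0)
        cluster_cf.push_back((double)bonded_multi / multi_pairs);
      e2e2.push_back(dist2(st.coords[0], st.coords[n_nodes - 1]));
      bound_endog.push_back(nbound_en);
      bound_exog.push_back(nbound_ex);
    }
  }

  IntegerMatrix cm(contact_count.size(), 3);
  int ri = 0;
  for (auto& kv : contact_count) {
    cm(ri, 0) = kv.first.first + 1;
    cm(ri, 1) = kv.first.second + 1;
    cm(ri, 2) = kv.second;
    ++ri;
  }
  colnames(cm) = CharacterVector::create("node_i", "node_j", "n_snapshots");

  return List::create(
      _["cluster_sizes"] = wrap(snapshots_sizes),
      _["contact_pairs"] = cm,
      _["n_snapshots"] = (int)snapshots_sizes.size(),
      _["ever_occupied"] = LogicalVector(ever_occ.begin(), ever_occ.end()),
      _["end_to_end_sq"] = NumericVector(e2e2.begin(), e2e2.end()),
      _["cluster_contact_freq"] =
          NumericVector(cluster_cf.begin(), cluster_cf.end()),
      _["bound_endog"] = IntegerVector(bound_endog.begin(), bound_endog.end()),
      _["bound_exog"] = IntegerVector(bound_exog.begin(), bound_exog.end()),
      _["accepted_pivot"] = acc_pivot, _["accepted_local"] = acc_local,
      _["final_state"] = state_to_list(st));
}
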