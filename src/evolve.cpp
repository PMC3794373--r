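// Stochastic engine for the four-process network evolution model.
//
// Per unit time: (1) a new node arrives with c edges whose targets are drawn
// with weight a + b*k; (2) m internal edges are added, each endpoint drawn
// independently with weight s + t*k; (3) with probability r one uniformly
// random node is deleted with all incident edges; (4) with probability q,
// m uniformly random edges are deleted.
//
// Degree-proportional draws use the mixture identity
//   P(v) ~ rand + pref*deg(v)
//   = [rand*n / (rand*n + pref*2e)] * uniform-node
//   + [pref*2e / (...)]            * uniform-endpoint-of-uniform-edge,
// so no weight vector is ever materialized. Uses R's RNG: runs are fully
// reproducible from set.seed().

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <utility>

using namespace Rcpp;

static const long long REJECT_CAP = 1000000LL;

static inline long long ekey(int u, int v) {
  if (u > v) std::swap(u, v);
  return (static_cast<long long>(u) << 32) | static_cast<unsigned int>(v);
}

namespace {

struct EvoState {
  std::vector<std::unordered_set<int>> adj;  // by node id (ids never reused)
  std::vector<int> alive;                    // current node ids
  std::vector<int> pos;                      // id -> index in alive, -1 if gone
  std::vector<std::pair<int, int>> edges;    // current edge list
  std::unordered_map<long long, int> epos;   // edge key -> index in edges
  long long rejections = 0;

  int n() const { return static_cast<int>(alive.size()); }
  long long e() const { return static_cast<long long>(edges.size()); }

  int add_node() {
    int id = static_cast<int>(adj.size());
    adj.emplace_back();
    pos.push_back(static_cast<int>(alive.size()));
    alive.push_back(id);
    return id;
  }

  bool has_edge(int u, int v) const {
    return epos.find(ekey(u, v)) != epos.end();
  }

  void add_edge(int u, int v) {
    adj[u].insert(v);
    adj[v].insert(u);
    epos[ekey(u, v)] = static_cast<int>(edges.size());
    edges.emplace_back(u, v);
  }

  void remove_edge_at(int idx) {
    std::pair<int, int> ed = edges[idx];
    adj[ed.first].erase(ed.second);
    adj[ed.second].erase(ed.first);
    epos.erase(ekey(ed.first, ed.second));
    int last = static_cast<int>(edges.size()) - 1;
    if (idx != last) {
      edges[idx] = edges[last];
      epos[ekey(edges[idx].first, edges[idx].second)] = idx;
    }
    edges.pop_back();
  }

  void remove_edge(int u, int v) {
    remove_edge_at(epos.at(ekey(u, v)));
  }

  void delete_node(int u) {
    std::vector<int> nb(adj[u].begin(), adj[u].end());
    for (int v : nb) remove_edge(u, v);
    int idx = pos[u], last = static_cast<int>(alive.size()) - 1;
    if (idx != last) {
      alive[idx] = alive[last];
      pos[alive[idx]] = idx;
    }
    alive.pop_back();
    pos[u] = -1;
  }

  int uniform_alive() const {
    int i = static_cast<int>(unif_rand() * n());
    if (i >= n()) i = n() - 1;
    return alive[i];
  }

  // One draw with P(v) proportional to rand + pref*deg(v); -1 if total weight 0.
  int sample_one(double rand_c, double pref_c) const {
    double tr = rand_c * n();
    double tp = pref_c * 2.0 * static_cast<double>(e());
    double tot = tr + tp;
    if (tot <= 0.0) return -1;
    if (unif_rand() * tot < tr) return uniform_alive();
    int i = static_cast<int>(unif_rand() * e());
    if (i >= static_cast<int>(e())) i = static_cast<int>(e()) - 1;
    const std::pair<int, int>& ed = edges[i];
    return (unif_rand() < 0.5) ? ed.first : ed.second;
  }

  // `count` distinct draws, rejecting duplicates and `exclude` with redraw.
  std::vector<int> sample_distinct(double rand_c, double pref_c, int count,
                                   int exclude) {
    std::vector<int> out;
    std::unordered_set<int> seen;
    long long consec = 0;
    while (static_cast<int>(out.size()) < count) {
      int v = sample_one(rand_c, pref_c);
      if (v < 0)
        stop("degree-biased draw undefined: total sampling weight is zero "
             "(n=%d, e=%d)", n(), (int)e());
      if (v == exclude || seen.count(v)) {
        rejections++;
        if (++consec > REJECT_CAP)
          stop("more than %d consecutive rejected draws (n=%d, e=%d): "
               "pathological configuration", (int)REJECT_CAP, n(), (int)e());
        continue;
      }
      consec = 0;
      seen.insert(v);
      out.push_back(v);
    }
    return out;
  }

  void validate() const {
    long long degsum = 0;
    for (int id : alive) degsum += static_cast<long long>(adj[id].size());
    if (degsum != 2 * e())
      stop("invariant violated: sum of degrees != 2e");
    if (epos.size() != edges.size())
      stop("invariant violated: edge index out of sync");
    for (const auto& ed : edges) {
      if (ed.first == ed.second) stop("invariant violated: self-loop");
      if (pos[ed.first] < 0 || pos[ed.second] < 0)
        stop("invariant violated: edge incident to deleted node");
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_evolve(int c, int m, double r, double q, double a, double b,
                double s, double t, int n_target, IntegerMatrix init_edges,
                int init_nodes, bool check_each_step) {
  RNGScope scope;
  EvoState g;
  for (int i = 0; i < init_nodes; i++) g.add_node();
  for (int i = 0; i < init_edges.nrow(); i++)
    g.add_edge(init_edges(i, 0), init_edges(i, 1));

  long long steps = 0, nodes_deleted = 0, edges_deleted = 0,
            internal_added = 0, external_added = 0;

  while (g.n() < n_target) {
    steps++;
    // (1) node addition: targets drawn among pre-existing nodes only
    int cc = std::min(c, g.n());
    std::vector<int> targets = g.sample_distinct(a, b, cc, -1);
    int id = g.add_node();
    for (int v : targets) {
      g.add_edge(id, v);
      external_added++;
    }
    // (2) internal edges (the new node is eligible); skip when the graph is
    // complete and no further simple edge exists
    for (int j = 0; j < m; j++) {
      long long nn = g.n();
      if (g.e() >= nn * (nn - 1) / 2) break;
      long long consec = 0;
      int u, v;
      for (;;) {
        u = g.sample_one(s, t);
        v = g.sample_one(s, t);
        if (u < 0 || v < 0)
          stop("internal-edge draw undefined: total sampling weight is zero");
        if (u != v && !g.has_edge(u, v)) break;
        g.rejections++;
        if (++consec > REJECT_CAP)
          stop("more than %d consecutive rejected internal-edge draws "
               "(n=%d, e=%d)", (int)REJECT_CAP, g.n(), (int)g.e());
      }
      g.add_edge(u, v);
      internal_added++;
    }
    // (3) node deletion
    if (r > 0.0 && unif_rand() < r) {
      if (g.n() == 0) stop("node deletion from an empty graph");
      g.delete_node(g.uniform_alive());
      nodes_deleted++;
    }
    // (4) edge deletion: m uniformly random edges (fewer if fewer exist)
    if (q > 0.0 && unif_rand() < q) {
      for (int j = 0; j < m; j++) {
        if (g.e() == 0) break;
        int i = static_cast<int>(unif_rand() * g.e());
        if (i >= static_cast<int>(g.e())) i = static_cast<int>(g.e()) - 1;
        g.remove_edge_at(i);
        edges_deleted++;
      }
    }
    if (check_each_step) g.validate();
  }
  g.validate();

  IntegerMatrix em(g.e(), 2);
  for (long long i = 0; i < g.e(); i++) {
    int u = g.edges[i].first, v = g.edges[i].second;
    em(i, 0) = std::min(u, v);
    em(i, 1) = std::max(u, v);
  }
  IntegerVector ids(g.n()), degs(g.n());
  std::vector<int> sorted(g.alive);
  std::sort(sorted.begin(), sorted.end());
  for (int i = 0; i < g.n(); i++) {
    ids[i] = sorted[i];
    degs[i] = static_cast<int>(g.adj[sorted[i]].size());
  }

  return List::create(
      _["edges"] = em, _["node_ids"] = ids, _["degrees"] = degs,
      _["n"] = g.n(), _["e"] = static_cast<double>(g.e()),
      _["steps"] = static_cast<double>(steps),
      _["nodes_deleted"] = static_cast<double>(nodes_deleted),
      _["edges_deleted"] = static_cast<double>(edges_deleted),
      _["internal_edges_added"] = static_cast<double>(internal_added),
      _["external_edges_added"] = static_cast<double>(external_added),
      _["rejections"] = static_cast<double>(g.rejections),
      _["next_id"] = static_cast<int>(g.adj.size()));
}
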