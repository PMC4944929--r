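// Greedy two-level map-equation minimization (Louvain-style search).
//
// Undirected weighted graphs only; node visit rates are the
// strength-proportional stationary distribution, so no teleportation is
// needed. Node moves and module aggregations are accepted when they lower
// the codelength
//   L = plogp(q) - 2*sum_m plogp(q_m) + sum_m plogp(p_m + q_m)
//       - sum_i plogp(p_i),
// with plogp(x) = x log2 x and all flows in units of total stationary flow.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

namespace {

inline double plogp(double x) { return x > 1e-15 ? x * std::log2(x) : 0.0; }

struct Graph {
  int n;
  std::vector<std::vector<std::pair<int, double>>> adj;  // neighbor, flow
  std::vector<double> p;      // node flow (strength / total stationary flow)
  std::vector<double> self;   // internal (self-loop) flow of supernodes
};

struct ModuleState {
  std::vector<int> mod;       // module of each node
  std::vector<double> p_mod;  // internal flow per module
  std::vector<double> q_mod;  // exit flow per module
  double q_tot;
  double sum_plogp_q;         // sum_m plogp(q_m)
  double sum_plogp_pq;        // sum_m plogp(p_m + q_m)

  double codelength(double node_term) const {
    return plogp(q_tot) - 2.0 * sum_plogp_q + sum_plogp_pq - node_term;
  }
};

ModuleState init_singletons(const Graph& g) {
  ModuleState st;
  st.mod.resize(g.n);
  st.p_mod.resize(g.n);
  st.q_mod.resize(g.n);
  st.q_tot = 0.0;
  st.sum_plogp_q = 0.0;
  st.sum_plogp_pq = 0.0;
  for (int i = 0; i < g.n; ++i) {
    st.mod[i] = i;
    st.p_mod[i] = g.p[i];
    double x = 0.0;
    for (auto& e : g.adj[i]) x += e.second;  // self-loops are not in adj
    st.q_mod[i] = x;
    st.q_tot += x;
    st.sum_plogp_q += plogp(x);
    st.sum_plogp_pq += plogp(g.p[i] + x);
  }
  return st;
}

// deterministic Fisher-Yates (avoids std::shuffle's library dependence)
void shuffle_ints(std::vector<int>& v, std::mt19937& rng) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(rng() % (unsigned)(i + 1));
    std::swap(v[i], v[j]);
  }
}

// one pass of local moves in random order; returns true if anything moved
bool local_move_pass(const Graph& g, ModuleState& st, std::mt19937& rng) {
  std::vector<int> order(g.n);
  for (int i = 0; i < g.n; ++i) order[i] = i;
  shuffle_ints(order, rng);

  std::vector<double> flow_to(g.n, 0.0);
  std::vector<int> touched;
  bool any = false;

  for (int oi = 0; oi < g.n; ++oi) {
    int v = order[oi];
    int a = st.mod[v];
    double x_v = 0.0;
    touched.clear();
    for (auto& e : g.adj[v]) {
      int m = st.mod[e.first];
      if (flow_to[m] == 0.0) touched.push_back(m);
      flow_to[m] += e.second;
      x_v += e.second;
    }
    double e_va = flow_to[a];  // flow from v to the rest of its module

    double qa_new = st.q_mod[a] - x_v + 2.0 * e_va;
    double pa_new = st.p_mod[a] - g.p[v];

    double best_delta = -1e-12;
    int best_mod = a;
    for (size_t ti = 0; ti < touched.size(); ++ti) {
      int b = touched[ti];
      if (b == a) continue;
      double e_vb = flow_to[b];
      double qb_new = st.q_mod[b] + x_v - 2.0 * e_vb;
      double pb_new = st.p_mod[b] + g.p[v];
      double q_new = st.q_tot + 2.0 * (e_va - e_vb);
      double delta =
          (plogp(q_new) - plogp(st.q_tot)) -
          2.0 * (plogp(qa_new) + plogp(qb_new) -
                 plogp(st.q_mod[a]) - plogp(st.q_mod[b])) +
          (plogp(qa_new + pa_new) + plogp(qb_new + pb_new) -
           plogp(st.q_mod[a] + st.p_mod[a]) -
           plogp(st.q_mod[b] + st.p_mod[b]));
      if (delta < best_delta) {
        best_delta = delta;
        best_mod = b;
      }
    }

    if (best_mod != a) {
      int b = best_mod;
      double e_vb = flow_to[b];
      double qb_new = st.q_mod[b] + x_v - 2.0 * e_vb;
      double pb_new = st.p_mod[b] + g.p[v];
      st.sum_plogp_q += plogp(qa_new) + plogp(qb_new) -
                        plogp(st.q_mod[a]) - plogp(st.q_mod[b]);
      st.sum_plogp_pq += plogp(qa_new + pa_new) + plogp(qb_new + pb_new) -
                         plogp(st.q_mod[a] + st.p_mod[a]) -
                         plogp(st.q_mod[b] + st.p_mod[b]);
      st.q_mod[a] = qa_new;
      st.p_mod[a] = pa_new;
      st.q_mod[b] = qb_new;
      st.p_mod[b] = pb_new;
      st.q_tot += 2.0 * (e_va - e_vb);
      st.mod[v] = b;
      any = true;
    }
    for (size_t k = 0; k < touched.size(); ++k) flow_to[touched[k]] = 0.0;
  }
  return any;
}

// aggregate modules into supernodes; dense_label maps node -> supernode
Graph aggregate(const Graph& g, const std::vector<int>& mod,
                std::vector<int>& dense_label) {
  dense_label.assign(g.n, -1);
  std::vector<int> lab_of(g.n, -1);
  int next = 0;
  for (int i = 0; i < g.n; ++i) {
    int m = mod[i];
    if (lab_of[m] < 0) lab_of[m] = next++;
    dense_label[i] = lab_of[m];
  }
  Graph h;
  h.n = next;
  h.adj.assign(next, {});
  h.p.assign(next, 0.0);
  h.self.assign(next, 0.0);
  std::vector<std::vector<std::pair<int, double>>> buckets(next);
  for (int i = 0; i < g.n; ++i) {
    int a = dense_label[i];
    h.p[a] += g.p[i];
    h.self[a] += g.self[i];
    for (auto& e : g.adj[i]) {
      int b = dense_label[e.first];
      if (a == b) {
        h.self[a] += e.second / 2.0;  // internal edge, seen from both ends
      } else {
        buckets[a].push_back(std::make_pair(b, e.second));
      }
    }
  }
  for (int a = 0; a < next; ++a) {
    std::vector<std::pair<int, double>>& v = buckets[a];
    std::sort(v.begin(), v.end());
    for (size_t k = 0; k < v.size();) {
      size_t k2 = k;
      double s = 0.0;
      while (k2 < v.size() && v[k2].first == v[k].first) s += v[k2++].second;
      h.adj[a].push_back(std::make_pair(v[k].first, s));
      k = k2;
    }
  }
  return h;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List infomap_core(int n, Rcpp::IntegerVector ei, Rcpp::IntegerVector ej,
                        Rcpp::NumericVector w, int trials, int seed) {
  double two_w = 0.0;
  for (int k = 0; k < ei.size(); ++k) two_w += 2.0 * w[k];
  if (two_w <= 0) Rcpp::stop("graph has no positive-weight links");

  Graph g0;
  g0.n = n;
  g0.adj.assign(n, {});
  g0.p.assign(n, 0.0);
  g0.self.assign(n, 0.0);
  for (int k = 0; k < ei.size(); ++k) {
    if (ei[k] == ej[k]) Rcpp::stop("self-loops are not allowed");
    double f = w[k] / two_w;  // stationary flow along the edge, per direction
    g0.adj[ei[k]].push_back(std::make_pair((int)ej[k], f));
    g0.adj[ej[k]].push_back(std::make_pair((int)ei[k], f));
    g0.p[ei[k]] += f;
    g0.p[ej[k]] += f;
  }
  double node_term = 0.0;
  for (int i = 0; i < n; ++i) node_term += plogp(g0.p[i]);

  std::vector<int> best_mod(n);
  for (int i = 0; i < n; ++i) best_mod[i] = i;
  double best_L = R_PosInf;

  for (int t = 0; t < trials; ++t) {
    std::mt19937 rng(static_cast<unsigned>(seed) * 1000003u +
                     static_cast<unsigned>(t));
    std::vector<int> node_lab(n);
    for (int i = 0; i < n; ++i) node_lab[i] = i;
    Graph g = g0;
    double L;

    while (true) {
      ModuleState st = init_singletons(g);
      while (local_move_pass(g, st, rng)) {
      }
      L = st.codelength(node_term);
      std::vector<int> dense;
      Graph h = aggregate(g, st.mod, dense);
      for (int i = 0; i < n; ++i) node_lab[i] = dense[node_lab[i]];
      if (h.n == g.n) break;  // nothing merged: converged
      g = h;
    }

    if (L < best_L - 1e-12) {
      best_L = L;
      best_mod = node_lab;
    }
  }

  return Rcpp::List::create(Rcpp::Named("membership") = best_mod,
                            Rcpp::Named("codelength") = best_L);
}
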