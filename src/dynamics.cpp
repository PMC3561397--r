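#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Adjacency is CSR over 0-based agent ids: neighbours of agent i are
// idx[ptr[i] .. ptr[i+1]-1]. All randomness comes from R's RNG (unif_rand),
// drawn in increasing agent-id order, so R-level set.seed() governs
// everything and the R reference step is bit-comparable.

// Count of neighbours sharing agent i's action, for every agent.
// [[Rcpp::export]]
IntegerVector same_counts_cpp(IntegerVector ptr, IntegerVector idx,
                              IntegerVector actions) {
  const int n = ptr.size() - 1;
  IntegerVector same(n);
  for (int i = 0; i < n; ++i) {
    int cnt = 0, ai = actions[i];
    for (int k = ptr[i]; k < ptr[i + 1]; ++k)
      if (actions[idx[k]] == ai) ++cnt;
    same[i] = cnt;
  }
  return same;
}

// satisfied <=> liked/degree >= 1/2 <=> 2*liked >= degree; degree 0 counts
// as satisfied (vacuous preference).
static inline bool is_satisfied(int same, int deg, int type) {
  if (deg == 0) return true;
  int liked = (type == 0) ? same : deg - same;
  return 2 * liked >= deg;
}

static void state_indices(const std::vector<int>& same, IntegerVector ptr,
                          IntegerVector types, double* out) {
  const int n = (int)same.size();
  int nsat = 0, ncomp = 0;
  double sumsat = 0.0;
  for (int i = 0; i < n; ++i) {
    int deg = ptr[i + 1] - ptr[i];
    int liked = deg == 0 ? 0 : (types[i] == 0 ? same[i] : deg - same[i]);
    double s = deg == 0 ? 1.0 : (double)liked / deg;
    sumsat += s;
    if (deg == 0 || 2 * liked >= deg) ++nsat;
    if (deg == 0 || liked == deg) ++ncomp;
  }
  out[0] = (double)nsat / n;   // cooperation degree
  out[1] = sumsat / n;         // average satisfaction degree
  out[2] = (double)ncomp / n;  // complete ratio
}

// The stochastic best-response dynamic. Each step, every agent's
// satisfaction is evaluated against the previous profile; each unsatisfied
// agent then flips with probability p, simultaneously. sequential = TRUE
// instead flips exactly one uniformly chosen unsatisfied agent per step
// (the asynchronous, vanishing-p limit).
// [[Rcpp::export]]
List run_dynamics_cpp(IntegerVector ptr, IntegerVector idx, IntegerVector types,
                      IntegerVector actions, double p, int max_steps,
                      bool stop_at_nash, bool record_series, bool sequential) {
  const int n = ptr.size() - 1;
  std::vector<int> act(actions.begin(), actions.end());
  std::vector<int> same(n), unsat;
  unsat.reserve(n);
  std::vector<double> series;
  if (record_series) series.reserve(3 * (max_steps + 1));

  RNGScope scope;
  int steps = 0, first_nash = -1;
  bool nash = false;

  for (;;) {
    // satisfaction against the current (previous-step) profile
    unsat.clear();
    for (int i = 0; i < n; ++i) {
      int cnt = 0, ai = act[i];
      for (int k = ptr[i]; k < ptr[i + 1]; ++k)
        if (act[idx[k]] == ai) ++cnt;
      same[i] = cnt;
      if (!is_satisfied(cnt, ptr[i + 1] - ptr[i], types[i])) unsat.push_back(i);
    }
    if (record_series && steps == 0) {
      double out[3];
      state_indices(same, ptr, types, out);
      series.insert(series.end(), out, out + 3);
    }
    if (unsat.empty()) {
      nash = true;
      if (first_nash < 0) first_nash = steps;
      if (stop_at_nash) break;
    }
    if (steps >= max_steps) break;

    if (!unsat.empty()) {
      if (sequential) {
        int j = (int)(unif_rand() * unsat.size());
        if (j >= (int)unsat.size()) j = (int)unsat.size() - 1;
        act[unsat[j]] ^= 1;
      } else {
        // draws in increasing agent-id order over the unsatisfied set
        for (size_t u = 0; u < unsat.size(); ++u)
          if (unif_rand() < p) act[unsat[u]] ^= 1;
      }
    }
    ++steps;

    if (record_series) {
      for (int i = 0; i < n; ++i) {
        int cnt = 0, ai = act[i];
        for (int k = ptr[i]; k < ptr[i + 1]; ++k)
          if (act[idx[k]] == ai) ++cnt;
        same[i] = cnt;
      }
      double out[3];
      state_indices(same, ptr, types, out);
      series.insert(series.end(), out, out + 3);
    }
  }

  // final indices from the last computed profile
  for (int i = 0; i < n; ++i) {
    int cnt = 0, ai = act[i];
    for (int k = ptr[i]; k < ptr[i + 1]; ++k)
      if (act[idx[k]] == ai) ++cnt;
    same[i] = cnt;
  }
  double fin[3];
  state_indices(same, ptr, types, fin);

  List res = List::create(
      _["actions"] = IntegerVector(act.begin(), act.end()),
      _["steps_run"] = steps, _["reached_nash"] = nash,
      _["first_nash_step"] =
          first_nash < 0 ? IntegerVector::create(NA_INTEGER)
                         : IntegerVector::create(first_nash),
      _["cooperation_degree"] = fin[0], _["avg_satisfaction"] = fin[1],
      _["complete_ratio"] = fin[2]);
  if (record_series) {
    int nr = (int)series.size() / 3;
    NumericMatrix m(nr, 3);
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < 3; ++c) m(r, c) = series[3 * r + c];
    res["series"] = m;
  } else {
    res["series"] = R_NilValue;
  }
  return res;
}

// Watts-Strogatz style rewiring: each edge is independently selected with
// probability q (drawn in stored edge order); a selected edge keeps its
// smaller endpoint and redraws the other uniformly over agents, rejecting
// self-loops and edges already present; after max_retry rejections the
// edge is left in place. Edge count is conserved exactly.
// [[Rcpp::export]]
IntegerMatrix rewire_cpp(int n, IntegerMatrix edges, double q, int max_retry) {
  const int m = edges.nrow();
  IntegerMatrix out(m, 2);
  std::unordered_set<long long> present;
  present.reserve(2 * m);
  auto key = [n](int a, int b) {
    if (a > b) std::swap(a, b);
    return (long long)a * n + b;
  };
  for (int e = 0; e < m; ++e) {
    out(e, 0) = edges(e, 0);
    out(e, 1) = edges(e, 1);
    present.insert(key(edges(e, 0), edges(e, 1)));
  }
  RNGScope scope;
  for (int e = 0; e < m; ++e) {
    if (unif_rand() >= q) continue;
    int a = out(e, 0), b = out(e, 1);
    int keep = std::min(a, b), old_other = std::max(a, b);
    present.erase(key(keep, old_other));
    int chosen = -1;
    for (int t = 0; t < max_retry; ++t) {
      int cand = (int)(unif_rand() * n);
      if (cand >= n) cand = n - 1;
      if (cand == keep) continue;
      if (present.count(key(keep, cand))) continue;
      chosen = cand;
      break;
    }
    if (chosen < 0) chosen = old_other;  // saturated / unlucky: leave in place
    out(e, 0) = keep;
    out(e, 1) = chosen;
    present.insert(key(keep, chosen));
  }
  return out;
}

// CSR adjacency from an edge list, O(n + m).
// [[Rcpp::export]]
List build_csr_cpp(int n, IntegerMatrix edges) {
  const int m = edges.nrow();
  IntegerVector ptr(n + 1);
  IntegerVector idx(2 * m);
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    ++deg[edges(e, 0)];
    ++deg[edges(e, 1)];
  }
  for (int i = 0; i < n; ++i) ptr[i + 1] = ptr[i] + deg[i];
  std::vector<int> pos(n);
  for (int i = 0; i < n; ++i) pos[i] = ptr[i];
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    idx[pos[a]++] = b;
    idx[pos[b]++] = a;
  }
  return List::create(_["ptr"] = ptr, _["idx"] = idx);
}
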