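#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Depth-first enumeration of aggression chains: directed paths of n edges
// over nonzero entries of d with all nodes pairwise distinct. Accumulates
// in one pass the sums needed for the weighted rank difference W(n) and
// fractional transitivity T(n):
//   W(n) = sum_chains prod(d_edges) * (rank(terminal) - rank(origin))
//        / sum_chains prod(d_edges)
//   T(n) = sum_chains prod(d_edges) * (d(origin,terminal) - dbar) / dbar
//        / sum_chains prod(d_edges)
// where dbar is the origin's mean aggression toward all individuals other
// than the chain's interior members (baseline_mode 0) or other than the
// first intermediate only (baseline_mode 1). Chains with dbar == 0 are
// excluded from the T sums and counted, unless baseline_eps > 0 is added.

struct ChainState {
  const double* d;
  const int* ranks;
  int N;
  int n;
  int baseline_mode;
  double baseline_eps;
  const std::vector<std::vector<int> >* adj;
  const double* rowsum;
  std::vector<char> visited;
  int origin;
  int first_intermediate;
  double w_num, w_den, t_num, t_den;
  double chains, zero_baseline;
  long long visits, max_visits;
};

static void chain_dfs(ChainState& st, int cur, int depth, double wprod,
                      double interior_sum) {
  if (++st.visits > st.max_visits) {
    stop("chain enumeration exceeded max_visits (%s); reduce n or raise the cap",
         std::to_string(st.max_visits));
  }
  if (depth == st.n) {
    const int o = st.origin;
    st.chains += 1;
    st.w_num += wprod * (st.ranks[cur] - st.ranks[o]);
    st.w_den += wprod;
    if (st.n >= 2) {
      double base, denom;
      if (st.baseline_mode == 0) {
        base = st.rowsum[o] - interior_sum;
        denom = st.N - 1 - (st.n - 1);
      } else {
        base = st.rowsum[o] - st.d[o + st.first_intermediate * st.N];
        denom = st.N - 2;
      }
      double dbar = (denom > 0 ? base / denom : 0.0) + st.baseline_eps;
      if (dbar > 0) {
        double dik = st.d[o + cur * st.N];
        st.t_num += wprod * (dik - dbar) / dbar;
        st.t_den += wprod;
      } else {
        st.zero_baseline += 1;
      }
    }
    return;
  }
  const std::vector<int>& nb = (*st.adj)[cur];
  for (size_t a = 0; a < nb.size(); ++a) {
    int nxt = nb[a];
    if (st.visited[nxt]) continue;
    double w = st.d[cur + nxt * st.N];
    int nd = depth + 1;
    st.visited[nxt] = 1;
    if (nd == 1) st.first_intermediate = nxt;
    // node at position nd is interior iff nd < n
    double add = (nd < st.n) ? st.d[st.origin + nxt * st.N] : 0.0;
    chain_dfs(st, nxt, nd, wprod * w, interior_sum + add);
    st.visited[nxt] = 0;
  }
}

// [[Rcpp::export]]
List chain_stats_cpp(NumericMatrix d, IntegerVector ranks, int n,
                     int baseline_mode = 0, double baseline_eps = 0.0,
                     double max_visits = 5e9) {
  int N = d.nrow();
  if (d.ncol() != N) stop("d must be square");
  if (ranks.size() != N) stop("ranks length must match d");
  if (n < 1) stop("n must be at least 1");
  if (n > N - 1) stop("chain of %d edges needs %d distinct individuals", n, n + 1);

  std::vector<std::vector<int> > adj(N);
  std::vector<double> rowsum(N, 0.0);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      if (i == j) continue;
      double w = d(i, j);
      if (w < 0 || !R_finite(w)) stop("d must be finite and non-negative");
      rowsum[i] += w;
      if (w > 0) adj[i].push_back(j);
    }
  }

  ChainState st;
  st.d = d.begin();
  st.ranks = ranks.begin();
  st.N = N;
  st.n = n;
  st.baseline_mode = baseline_mode;
  st.baseline_eps = baseline_eps;
  st.adj = &adj;
  st.rowsum = rowsum.data();
  st.visited.assign(N, 0);
  st.w_num = st.w_den = st.t_num = st.t_den = 0.0;
  st.chains = st.zero_baseline = 0.0;
  st.visits = 0;
  st.max_visits = (long long)max_visits;

  for (int i = 0; i < N; ++i) {
    if (adj[i].empty()) continue;
    st.origin = i;
    st.first_intermediate = -1;
    st.visited[i] = 1;
    chain_dfs(st, i, 0, 1.0, 0.0);
    st.visited[i] = 0;
  }

  // n == 1 has a single edge; chains with the edge present all count
  return List::create(
    _["w_num"] = st.w_num, _["w_den"] = st.w_den,
    _["t_num"] = st.t_num, _["t_den"] = st.t_den,
    _["chains"] = st.chains, _["zero_baseline"] = st.zero_baseline
  );
}
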