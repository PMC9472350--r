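#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <vector>

using namespace Rcpp;

// Maximal-chain enumeration over seeds of one chromosome strand.
//
// Input seeds are sorted by position (ties by probe index).  A directed link
// i -> j exists when probe_j > probe_i, pos_j > pos_i and the observed gap
// pos_j - pos_i deviates from the expected gap cum[probe_j] - cum[probe_i]
// by at most t.  A chain is a path in this DAG; it is maximal when no single
// seed can be prepended, appended or inserted between two consecutive chain
// members while keeping every link valid.  Maximal chains are exactly the
// source-to-sink paths that use only "tight" links (links with no one-seed
// subdivision), which this routine enumerates with a length bound of m.

// [[Rcpp::export(name = ".cpp_chain_seeds")]]
List cpp_chain_seeds(IntegerVector pos, IntegerVector probe,
                     NumericVector cum, int t, int m, int cap) {
  const int n = pos.size();
  List empty(0);
  if (n == 0) return empty;

  // maximum plausible span of a single link
  double maxExp = 0;
  for (int i = 0; i < cum.size(); ++i) maxExp = std::max(maxExp, cum[i]);
  const double maxGap = maxExp + t;

  std::vector<std::vector<int>> out(n), in(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double gap = (double) pos[j] - pos[i];
      if (gap > maxGap) break;
      if (gap <= 0) continue;
      if (probe[j] <= probe[i]) continue;
      double expg = cum[probe[j] - 1] - cum[probe[i] - 1];
      if (std::abs(expg - gap) <= (double) t) {
        out[i].push_back(j);
        in[j].push_back(i);
      }
    }
  }

  // tight link u -> w: no v with u -> v and v -> w
  std::vector<std::vector<int>> tout(n);
  for (int u = 0; u < n; ++u) {
    for (int w : out[u]) {
      bool tight = true;
      // out[u] and in[w] are sorted ascending; intersect with two pointers
      const std::vector<int>& a = out[u];
      const std::vector<int>& b = in[w];
      size_t ia = 0, ib = 0;
      while (ia < a.size() && ib < b.size()) {
        if (a[ia] == b[ib]) { tight = false; break; }
        if (a[ia] < b[ib]) ++ia; else ++ib;
      }
      if (tight) tout[u].push_back(w);
    }
  }

  // longest tight path starting at each node (edges always go right)
  std::vector<int> lstart(n, 1);
  for (int v = n - 1; v >= 0; --v)
    for (int w : tout[v])
      lstart[v] = std::max(lstart[v], 1 + lstart[w]);

  // DFS over tight links from every source, emitting paths at sinks
  std::vector<std::vector<int>> chains;
  bool capped = false;
  std::vector<int> path;
  std::function<void(int)> dfs = [&](int v) {
    if ((int) chains.size() >= cap) { capped = true; return; }
    path.push_back(v);
    if (out[v].empty()) { // sink in the full link graph
      if ((int) path.size() >= m) chains.push_back(path);
    } else {
      for (int w : tout[v])
        if ((int) path.size() + lstart[w] >= m) dfs(w);
    }
    path.pop_back();
  };
  for (int v = 0; v < n; ++v) {
    if (in[v].empty() && lstart[v] >= m) dfs(v);
    if (capped) break;
  }
  if (capped)
    Rf_warning("chain enumeration cap reached; seed set is pathologically dense");

  List res(chains.size());
  for (size_t i = 0; i < chains.size(); ++i) {
    IntegerVector ch(chains[i].size());
    for (size_t j = 0; j < chains[i].size(); ++j) ch[j] = chains[i][j] + 1;
    res[i] = ch;
  }
  return res;
}
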