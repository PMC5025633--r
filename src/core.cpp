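#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Normalized Hamming dissimilarity between all row pairs of an integer code
// matrix. NA_INTEGER marks a missing value.
//
// policy 0 ("pairwise_complete"): count mismatches over positions where both
//   values are observed, divide by the number of such positions; a pair with
//   no jointly observed position gets distance 1 and is counted in the
//   "degenerate_pairs" attribute so the caller can warn.
// policy 1 ("mismatch"): a position where either value is missing counts as a
//   mismatch; denominator is the full number of columns.
// [[Rcpp::export(name = ".hamming_core")]]
NumericMatrix hamming_core(IntegerMatrix x, int policy) {
  const int n = x.nrow(), J = x.ncol();
  NumericMatrix d(n, n);
  int degenerate = 0;
  for (int i = 0; i < n; ++i) {
    for (int k = i + 1; k < n; ++k) {
      int mism = 0, comp = 0;
      for (int j = 0; j < J; ++j) {
        const int a = x(i, j), b = x(k, j);
        const bool ma = (a == NA_INTEGER), mb = (b == NA_INTEGER);
        if (policy == 0) {
          if (!ma && !mb) {
            ++comp;
            if (a != b) ++mism;
          }
        } else {
          if (ma || mb || a != b) ++mism;
        }
      }
      double v;
      if (policy == 0) {
        if (comp == 0) {
          v = 1.0;
          ++degenerate;
        } else {
          v = static_cast<double>(mism) / comp;
        }
      } else {
        v = static_cast<double>(mism) / J;
      }
      d(i, k) = v;
      d(k, i) = v;
    }
  }
  d.attr("degenerate_pairs") = degenerate;
  return d;
}

// Agglomerative clustering with deterministic tie-breaking.
//
// Clusters carry node ids: leaves are 1..n, the cluster created at merge step
// s is n+s. At every step the candidate pair attaining the minimal linkage
// value with the lexicographically smallest (id_i, id_j), id_i < id_j, is
// merged. linkage: 0 average, 1 complete, 2 single.
//
// For average linkage the working statistic is the SUM of cross-cluster base
// distances (divided by the size product only when comparing), so the
// arithmetic performed is plain summation of entries of d0 — exactly
// reproducible by a from-scratch re-scan.
// [[Rcpp::export(name = ".agglom_core")]]
List agglom_core(NumericMatrix d0, int linkage) {
  const int n = d0.nrow();
  std::vector<double> S(d0.begin(), d0.end());
  std::vector<double> sz(n, 1.0);
  std::vector<int> node(n), code(n);
  std::vector<int> act;
  act.reserve(n);
  for (int i = 0; i < n; ++i) {
    node[i] = i + 1;
    code[i] = -(i + 1);
    act.push_back(i);
  }
  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);
  for (int step = 0; step < n - 1; ++step) {
    // act is sorted by node id (new nodes always get the largest id and are
    // appended), so scanning u < v visits pairs in lexicographic id order;
    // strict '<' keeps the first minimal pair.
    double best = R_PosInf;
    int pa = -1, pb = -1;
    const int m = static_cast<int>(act.size());
    for (int u = 0; u + 1 < m; ++u) {
      for (int v = u + 1; v < m; ++v) {
        const int a = act[u], b = act[v];
        double val = S[a + static_cast<size_t>(n) * b];
        if (linkage == 0) val /= sz[a] * sz[b];
        if (val < best) {
          best = val;
          pa = u;
          pb = v;
        }
      }
    }
    const int a = act[pa], b = act[pb];
    for (int u = 0; u < m; ++u) {
      const int c = act[u];
      if (c == a || c == b) continue;
      const double sac = S[a + static_cast<size_t>(n) * c];
      const double sbc = S[b + static_cast<size_t>(n) * c];
      double v;
      if (linkage == 0) v = sac + sbc;
      else if (linkage == 1) v = (sac > sbc) ? sac : sbc;
      else v = (sac < sbc) ? sac : sbc;
      S[a + static_cast<size_t>(n) * c] = v;
      S[c + static_cast<size_t>(n) * a] = v;
    }
    merge(step, 0) = code[a];
    merge(step, 1) = code[b];
    height[step] = best;
    sz[a] += sz[b];
    node[a] = n + step + 1;
    code[a] = step + 1;
    act.erase(act.begin() + pb);
    act.erase(act.begin() + pa);
    act.push_back(a);
  }
  return List::create(_["merge"] = merge, _["height"] = height);
}

// Fused agglomerate-then-cut used in the ensemble inner loops: runs the same
// deterministic agglomeration as agglom_core but stops after n-K merges and
// returns the canonical partition labels (cluster of the first observation
// is 1, next new cluster 2, ...). Heights are not materialized.
//
// Uses per-row minimum caches (row = active cluster; partners are the active
// clusters with larger node id) so a step costs O(m) plus a re-scan of the
// rows whose cached partner was consumed by the merge; the visiting order and
// strict '<' comparisons are identical to agglom_core's full scan, so the
// lexicographic tie contract — and hence the merge sequence — is preserved
// exactly.
// [[Rcpp::export(name = ".agglom_cut_core")]]
IntegerVector agglom_cut_core(NumericMatrix d0, int linkage, int K) {
  const int n = d0.nrow();
  if (K < 1 || K > n) stop("K out of range");
  std::vector<double> S(d0.begin(), d0.end());
  std::vector<double> sz(n, 1.0);
  std::vector<int> node(n);
  std::vector<std::vector<int> > members(n);
  std::vector<double> minval(n, R_PosInf);
  std::vector<int> minarg(n, -1);
  std::vector<int> act;
  act.reserve(n);
  for (int i = 0; i < n; ++i) {
    node[i] = i + 1;
    members[i].push_back(i);
    act.push_back(i);
  }
  // pair value under the linkage (average divides the maintained sum)
  #define PAIRVAL(a, b) (linkage == 0 \
    ? S[(a) + static_cast<size_t>(n) * (b)] / (sz[(a)] * sz[(b)]) \
    : S[(a) + static_cast<size_t>(n) * (b)])
  // cache for the row at position u: first minimum over later positions
  const auto recompute = [&](int u) {
    const int c = act[u];
    double best = R_PosInf;
    int barg = -1;
    const int m = static_cast<int>(act.size());
    for (int v = u + 1; v < m; ++v) {
      const double val = PAIRVAL(c, act[v]);
      if (val < best) {
        best = val;
        barg = act[v];
      }
    }
    minval[c] = best;
    minarg[c] = barg;
  };
  for (int u = 0; u + 1 < n; ++u) recompute(u);
  const int steps = n - K;
  for (int step = 0; step < steps; ++step) {
    const int m = static_cast<int>(act.size());
    double best = R_PosInf;
    int pa = -1;
    for (int u = 0; u + 1 < m; ++u) {
      if (minval[act[u]] < best) {
        best = minval[act[u]];
        pa = u;
      }
    }
    const int a = act[pa], b = minarg[a];
    int pb = -1;
    for (int v = pa + 1; v < m; ++v) {
      if (act[v] == b) {
        pb = v;
        break;
      }
    }
    for (int u = 0; u < m; ++u) {
      const int c = act[u];
      if (c == a || c == b) continue;
      const double sac = S[a + static_cast<size_t>(n) * c];
      const double sbc = S[b + static_cast<size_t>(n) * c];
      double v;
      if (linkage == 0) v = sac + sbc;
      else if (linkage == 1) v = (sac > sbc) ? sac : sbc;
      else v = (sac < sbc) ? sac : sbc;
      S[a + static_cast<size_t>(n) * c] = v;
      S[c + static_cast<size_t>(n) * a] = v;
    }
    members[a].insert(members[a].end(), members[b].begin(), members[b].end());
    members[b].clear();
    sz[a] += sz[b];
    node[a] = n + step + 1;
    act.erase(act.begin() + pb);
    act.erase(act.begin() + pa);
    act.push_back(a);
    // refresh caches: the merged cluster (largest id, last position) owns no
    // pairs; rows whose cached partner was a or b re-scan, the rest only
    // test the new cluster as a strictly better candidate
    minval[a] = R_PosInf;
    minarg[a] = -1;
    const int m2 = static_cast<int>(act.size());
    for (int u = 0; u + 1 < m2; ++u) {
      const int c = act[u];
      if (minarg[c] == a || minarg[c] == b) {
        recompute(u);
      } else {
        const double val = PAIRVAL(c, a);
        if (val < minval[c]) {
          minval[c] = val;
          minarg[c] = a;
        }
      }
    }
  }
  #undef PAIRVAL
  IntegerVector comp(n);
  for (size_t u = 0; u < act.size(); ++u) {
    for (size_t t = 0; t < members[act[u]].size(); ++t) {
      comp[members[act[u]][t]] = static_cast<int>(u) + 1;
    }
  }
  // canonicalize by first occurrence
  IntegerVector lab(n);
  std::vector<int> remap(act.size() + 1, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (remap[comp[i]] == 0) remap[comp[i]] = ++next;
    lab[i] = remap[comp[i]];
  }
  return lab;
}
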