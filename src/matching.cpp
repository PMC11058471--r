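// Matching solvers behind barcode distances: an O(n^3) assignment solver
// (Hungarian algorithm with potentials) for the Wasserstein distance, and
// the exact bottleneck distance by binary search over candidate costs with
// bipartite perfect-matching feasibility tests.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Minimum-cost perfect assignment on a square cost matrix.
// [[Rcpp::export]]
double assignment_cost_cpp(NumericMatrix cost) {
  int n = cost.nrow();
  if (n == 0) return 0.0;
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = 1e300;
  std::vector<double> C((size_t)n * n); // row-major copy for fast scans
  for (int i = 0; i < n; i++)
    for (int j = 0; j < n; j++) C[(size_t)i * n + j] = cost(i, j);
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  std::vector<double> minv(n + 1);
  std::vector<char> used(n + 1);
  for (int i = 1; i <= n; i++) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::fill(used.begin(), used.end(), 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      const double *row = &C[(size_t)(i0 - 1) * n];
      double ui0 = u[i0];
      for (int j = 1; j <= n; j++) {
        if (used[j]) continue;
        double cur = row[j - 1] - ui0 - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; j++) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  double total = 0.0;
  for (int j = 1; j <= n; j++) total += C[(size_t)(p[j] - 1) * n + (j - 1)];
  return total;
}

// ---- bottleneck ----
// Augmented bipartite graph: left = P intervals + n "diagonal copies",
// right = Q intervals + m "diagonal slots". Feasible at cost c iff a
// perfect matching exists using edges of cost <= c.
struct BtkGraph {
  int m, n; // |P|, |Q|
  const std::vector<double> *cij; // m x n row-major
  const std::vector<double> *dP;  // distance of P_i to diagonal
  const std::vector<double> *dQ;
  double c;
  inline bool edge(int l, int r) const {
    if (l < m) {
      if (r < n) return (*cij)[l * n + r] <= c;
      return (*dP)[l] <= c; // P_i -> any diagonal slot
    }
    if (r < n) return (*dQ)[r] <= c; // diagonal copy -> Q_j
    return true; // diagonal -> diagonal, cost 0
  }
};

static bool try_kuhn(const BtkGraph &g, int l, std::vector<int> &matchR,
                     std::vector<char> &seen) {
  int N = g.m + g.n;
  for (int r = 0; r < N; r++) {
    if (seen[r] || !g.edge(l, r)) continue;
    seen[r] = 1;
    if (matchR[r] == -1 || try_kuhn(g, matchR[r], matchR, seen)) {
      matchR[r] = l;
      return true;
    }
  }
  return false;
}

static bool feasible(BtkGraph &g, double c) {
  g.c = c;
  int N = g.m + g.n;
  std::vector<int> matchR(N, -1);
  for (int l = 0; l < N; l++) {
    std::vector<char> seen(N, 0);
    if (!try_kuhn(g, l, matchR, seen)) return false;
  }
  return true;
}

// Exact bottleneck distance between barcodes given as (birth, death) rows.
// [[Rcpp::export]]
double bottleneck_cpp(NumericMatrix P, NumericMatrix Q) {
  int m = P.nrow(), n = Q.nrow();
  if (m == 0 && n == 0) return 0.0;
  std::vector<double> cij(m * n), dP(m), dQ(n);
  for (int i = 0; i < m; i++) dP[i] = 0.5 * (P(i, 1) - P(i, 0));
  for (int j = 0; j < n; j++) dQ[j] = 0.5 * (Q(j, 1) - Q(j, 0));
  std::vector<double> cand;
  cand.push_back(0.0);
  for (int i = 0; i < m; i++)
    for (int j = 0; j < n; j++) {
      double c = std::max(std::fabs(P(i, 0) - Q(j, 0)),
                          std::fabs(P(i, 1) - Q(j, 1)));
      cij[i * n + j] = c;
      cand.push_back(c);
    }
  cand.insert(cand.end(), dP.begin(), dP.end());
  cand.insert(cand.end(), dQ.begin(), dQ.end());
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

  BtkGraph g;
  g.m = m; g.n = n; g.cij = &cij; g.dP = &dP; g.dQ = &dQ;
  int lo = 0, hi = (int)cand.size() - 1;
  if (!feasible(g, cand[hi])) stop("internal error: no feasible matching");
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (feasible(g, cand[mid])) hi = mid; else lo = mid + 1;
  }
  return cand[lo];
}
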