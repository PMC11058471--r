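// Persistence of a filtered simplicial complex over the field with two
// elements: standard left-to-right column reduction of the boundary matrix,
// with the twist (clearing) optimisation, processing dimensions in
// decreasing order. Ties in filtration value are broken by (dimension,
// lexicographic vertex tuple) so runs are reproducible bit-for-bit.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

// Symmetric difference of two ascending index vectors (GF(2) column add).
static void xor_into(std::vector<int> &a, const std::vector<int> &b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) out.push_back(a[i++]);
    else if (b[j] < a[i]) out.push_back(b[j++]);
    else { i++; j++; }
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
  a.swap(out);
}

// Input: flattened sorted vertex tuples, per-simplex dimension and value.
// Output: matrix with columns (dim, birth, death); death = +Inf for
// essential classes. Zero-persistence pairs are discarded.
// [[Rcpp::export]]
NumericMatrix persistence_cpp(IntegerVector dims, NumericVector values,
                              IntegerVector verts) {
  int m = dims.size();
  std::vector<std::vector<int> > sv(m);
  {
    int pos = 0;
    for (int i = 0; i < m; i++) {
      int w = dims[i] + 1;
      sv[i].assign(verts.begin() + pos, verts.begin() + pos + w);
      std::sort(sv[i].begin(), sv[i].end());
      pos += w;
    }
    if (pos != verts.size()) stop("vertex list length mismatch");
  }

  // Filtration order: (value, dim, lexicographic vertices).
  std::vector<int> ord(m);
  for (int i = 0; i < m; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (values[a] != values[b]) return values[a] < values[b];
    if (dims[a] != dims[b]) return dims[a] < dims[b];
    return sv[a] < sv[b];
  });
  std::vector<int> rank(m);
  for (int i = 0; i < m; i++) rank[ord[i]] = i;

  // Simplex lookup by vertex tuple (in filtration-order index space).
  std::map<std::vector<int>, int> key;
  for (int i = 0; i < m; i++) key[sv[ord[i]]] = i;

  // Boundary columns; verify the filtration property as we go.
  int maxd = 0;
  for (int i = 0; i < m; i++) maxd = std::max(maxd, (int)dims[i]);
  std::vector<std::vector<int> > bnd(m);
  for (int i = 0; i < m; i++) {
    int si = ord[i];
    int d = dims[si];
    if (d == 0) continue;
    std::vector<int> face(sv[si].size() - 1);
    for (size_t f = 0; f < sv[si].size(); f++) {
      size_t t = 0;
      for (size_t k = 0; k < sv[si].size(); k++)
        if (k != f) face[t++] = sv[si][k];
      std::map<std::vector<int>, int>::iterator it = key.find(face);
      if (it == key.end()) stop("face missing from filtered complex");
      if (it->second > i) stop("filtration property violated");
      bnd[i].push_back(it->second);
    }
    std::sort(bnd[i].begin(), bnd[i].end());
  }

  std::vector<int> pivot_owner(m, -1);
  std::vector<char> cleared(m, 0);
  std::vector<std::vector<int> > stored(m); // reduced columns kept as pivots
  std::vector<std::pair<int, int> > pairs;

  for (int d = maxd; d >= 1; d--) {
    for (int i = 0; i < m; i++) {
      if (dims[ord[i]] != d || cleared[i]) continue;
      std::vector<int> col = bnd[i];
      while (!col.empty()) {
        int low = col.back();
        int owner = pivot_owner[low];
        if (owner == -1) {
          pivot_owner[low] = i;
          cleared[low] = 1; // positive simplex: its own column need not reduce
          stored[i].swap(col);
          pairs.push_back(std::make_pair(low, i));
          break;
        }
        xor_into(col, stored[owner]);
      }
    }
  }

  // Essential classes: simplices never appearing as a pivot row whose own
  // column is zero (vertices always; higher dims when unpaired).
  std::vector<char> negative(m, 0); // simplices that destroy a class
  for (size_t p = 0; p < pairs.size(); p++) negative[pairs[p].second] = 1;
  std::vector<int> essential;
  for (int i = 0; i < m; i++) {
    if (pivot_owner[i] == -1 && !negative[i]) essential.push_back(i);
  }

  std::vector<double> ob, od;
  std::vector<int> ok_;
  for (size_t p = 0; p < pairs.size(); p++) {
    int bi = ord[pairs[p].first], di = ord[pairs[p].second];
    if (values[bi] == values[di]) continue;
    ok_.push_back(dims[bi]);
    ob.push_back(values[bi]);
    od.push_back(values[di]);
  }
  for (size_t e = 0; e < essential.size(); e++) {
    int bi = ord[essential[e]];
    ok_.push_back(dims[bi]);
    ob.push_back(values[bi]);
    od.push_back(R_PosInf);
  }

  NumericMatrix out((int)ok_.size(), 3);
  for (int i = 0; i < (int)ok_.size(); i++) {
    out(i, 0) = ok_[i];
    out(i, 1) = ob[i];
    out(i, 2) = od[i];
  }
  colnames(out) = CharacterVector::create("dim", "birth", "death");
  return out;
}
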