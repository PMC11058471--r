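// Filtered-complex construction: Vietoris-Rips by enumeration, alpha complex
// via incremental (Bowyer-Watson) 3D Delaunay triangulation with post-hoc
// empty-circumsphere verification, and alpha filtration values in squared
// circumradius units with Gabriel propagation.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

typedef std::array<double, 3> Pt;

static inline double sq(double x) { return x * x; }

static inline double dist2(const Pt &a, const Pt &b) {
  return sq(a[0] - b[0]) + sq(a[1] - b[1]) + sq(a[2] - b[2]);
}

// Circumcenter and squared circumradius of a tetrahedron.
// Returns false when the four points are (nearly) coplanar.
static bool tet_circum(const Pt &p0, const Pt &p1, const Pt &p2, const Pt &p3,
                       Pt &c, double &r2) {
  double A[3][3], b[3];
  const Pt *ps[3] = { &p1, &p2, &p3 };
  double n0 = sq(p0[0]) + sq(p0[1]) + sq(p0[2]);
  double amax = 0.0;
  for (int i = 0; i < 3; i++) {
    for (int j = 0; j < 3; j++) {
      A[i][j] = 2.0 * ((*ps[i])[j] - p0[j]);
      amax = std::max(amax, std::fabs(A[i][j]));
    }
    b[i] = (sq((*ps[i])[0]) + sq((*ps[i])[1]) + sq((*ps[i])[2])) - n0;
  }
  double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
             - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
             + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) <= 1e-14 * amax * amax * amax) return false;
  double x = (b[0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
            - A[0][1] * (b[1] * A[2][2] - A[1][2] * b[2])
            + A[0][2] * (b[1] * A[2][1] - A[1][1] * b[2])) / det;
  double y = (A[0][0] * (b[1] * A[2][2] - b[2] * A[1][2])
            - b[0] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
            + A[0][2] * (A[1][0] * b[2] - b[1] * A[2][0])) / det;
  double z = (A[0][0] * (A[1][1] * b[2] - A[2][1] * b[1])
            - A[0][1] * (A[1][0] * b[2] - b[1] * A[2][0])
            + b[0] * (A[1][0] * A[2][1] - A[1][1] * A[2][0])) / det;
  c[0] = x; c[1] = y; c[2] = z;
  r2 = dist2(c, p0);
  return true;
}

// Circumcenter (in the supporting plane) and squared circumradius of a
// triangle in 3D.
static bool tri_circum(const Pt &p0, const Pt &p1, const Pt &p2,
                       Pt &c, double &r2) {
  Pt u = { p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2] };
  Pt v = { p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2] };
  double a = u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
  double b = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
  double d = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
  double det = a * d - b * b;
  if (det <= 1e-28 * a * d || a == 0.0 || d == 0.0) return false;
  double s = (d * (a - b)) / (2.0 * det);
  double t = (a * (d - b)) / (2.0 * det);
  for (int j = 0; j < 3; j++) c[j] = p0[j] + s * u[j] + t * v[j];
  r2 = dist2(c, p0);
  return true;
}

struct Tet {
  int v[4];
  Pt c;
  double r2;
  bool alive;
};

// Incremental Delaunay. Returns list(tetra = m x 4 matrix (1-based),
// ok = logical, n_bad_sphere = verification failures).
// [[Rcpp::export]]
List delaunay_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("Delaunay triangulation needs at least 4 points");
  std::vector<Pt> P(n + 4);
  double lo[3] = { R_PosInf, R_PosInf, R_PosInf };
  double hi[3] = { R_NegInf, R_NegInf, R_NegInf };
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < 3; j++) {
      P[i][j] = pts(i, j);
      lo[j] = std::min(lo[j], P[i][j]);
      hi[j] = std::max(hi[j], P[i][j]);
    }
  }
  double cx[3], extent = 1e-6;
  for (int j = 0; j < 3; j++) {
    cx[j] = 0.5 * (lo[j] + hi[j]);
    extent = std::max(extent, hi[j] - lo[j]);
  }
  // Super-tetrahedron far outside the data; removed before returning.
  double L = 3e4 * extent;
  double dirs[4][3] = { {1, 1, 1}, {1, -1, -1}, {-1, 1, -1}, {-1, -1, 1} };
  for (int k = 0; k < 4; k++)
    for (int j = 0; j < 3; j++)
      P[n + k][j] = cx[j] + L * dirs[k][j];

  std::vector<Tet> tets;
  tets.reserve(16 * n);
  {
    Tet t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
    t0.alive = true;
    if (!tet_circum(P[n], P[n + 1], P[n + 2], P[n + 3], t0.c, t0.r2))
      stop("degenerate bounding tetrahedron");
    tets.push_back(t0);
  }

  std::vector<int> bad;
  bool ok = true;
  for (int i = 0; i < n && ok; i++) {
    bad.clear();
    for (size_t t = 0; t < tets.size(); t++) {
      if (tets[t].alive && dist2(P[i], tets[t].c) < tets[t].r2)
        bad.push_back((int)t);
    }
    if (bad.empty()) { ok = false; break; }
    // Boundary faces of the cavity appear in exactly one bad tetrahedron.
    std::map<std::array<int, 3>, int> fcount;
    for (int t : bad) {
      const int *v = tets[t].v;
      for (int f = 0; f < 4; f++) {
        std::array<int, 3> face;
        int m = 0;
        for (int k = 0; k < 4; k++) if (k != f) face[m++] = v[k];
        std::sort(face.begin(), face.end());
        fcount[face]++;
      }
    }
    for (int t : bad) tets[t].alive = false;
    for (std::map<std::array<int, 3>, int>::iterator it = fcount.begin();
         it != fcount.end(); ++it) {
      if (it->second != 1) continue;
      Tet nt;
      nt.v[0] = i;
      nt.v[1] = it->first[0]; nt.v[2] = it->first[1]; nt.v[3] = it->first[2];
      nt.alive = true;
      if (!tet_circum(P[nt.v[0]], P[nt.v[1]], P[nt.v[2]], P[nt.v[3]],
                      nt.c, nt.r2)) {
        ok = false;
        break;
      }
      tets.push_back(nt);
    }
  }

  std::vector<int> keep;
  if (ok) {
    for (size_t t = 0; t < tets.size(); t++) {
      if (!tets[t].alive) continue;
      bool real = true;
      for (int k = 0; k < 4; k++) if (tets[t].v[k] >= n) { real = false; break; }
      if (real) keep.push_back((int)t);
    }
    if (keep.empty()) ok = false;
  }

  // Verify the global Delaunay (empty circumsphere) property.
  int n_viol = 0;
  if (ok) {
    for (size_t kk = 0; kk < keep.size(); kk++) {
      const Tet &T = tets[keep[kk]];
      for (int j = 0; j < n; j++) {
        if (j == T.v[0] || j == T.v[1] || j == T.v[2] || j == T.v[3]) continue;
        if (dist2(P[j], T.c) < T.r2 * (1.0 - 1e-9)) { n_viol++; break; }
      }
    }
  }

  IntegerMatrix out(ok ? (int)keep.size() : 0, 4);
  if (ok) {
    for (size_t kk = 0; kk < keep.size(); kk++) {
      int v[4];
      for (int k = 0; k < 4; k++) v[k] = tets[keep[kk]].v[k];
      std::sort(v, v + 4);
      for (int k = 0; k < 4; k++) out(kk, k) = v[k] + 1;
    }
  }
  return List::create(_["tetra"] = out,
                      _["ok"] = ok && n_viol == 0,
                      _["n_bad_sphere"] = n_viol);
}

// Alpha complex: simplices of the Delaunay triangulation with filtration
// values in squared-circumradius units. Non-Gabriel faces inherit the
// minimum value of their cofaces.
// [[Rcpp::export]]
List alpha_values_cpp(NumericMatrix pts, IntegerMatrix tetra) {
  int n = pts.nrow();
  int nt = tetra.nrow();
  std::vector<Pt> P(n);
  for (int i = 0; i < n; i++)
    for (int j = 0; j < 3; j++) P[i][j] = pts(i, j);

  std::vector<double> tetval(nt);
  for (int t = 0; t < nt; t++) {
    Pt c; double r2;
    if (!tet_circum(P[tetra(t, 0) - 1], P[tetra(t, 1) - 1],
                    P[tetra(t, 2) - 1], P[tetra(t, 3) - 1], c, r2))
      stop("degenerate tetrahedron in Delaunay triangulation");
    tetval[t] = r2;
  }

  // Triangles: map sorted triple -> id, with (tet id, opposite vertex) list.
  typedef std::array<int, 3> Tri;
  std::map<Tri, int> trid;
  std::vector<Tri> tris;
  std::vector<std::vector<std::pair<int, int> > > tricof; // (tet, opp vertex)
  for (int t = 0; t < nt; t++) {
    int v[4] = { tetra(t, 0) - 1, tetra(t, 1) - 1,
                 tetra(t, 2) - 1, tetra(t, 3) - 1 };
    for (int f = 0; f < 4; f++) {
      Tri tr; int m = 0, opp = -1;
      for (int k = 0; k < 4; k++) {
        if (k == f) opp = v[k]; else tr[m++] = v[k];
      }
      std::sort(tr.begin(), tr.end());
      std::map<Tri, int>::iterator it = trid.find(tr);
      int id;
      if (it == trid.end()) {
        id = (int)tris.size();
        trid[tr] = id;
        tris.push_back(tr);
        tricof.push_back(std::vector<std::pair<int, int> >());
      } else id = it->second;
      tricof[id].push_back(std::make_pair(t, opp));
    }
  }

  int ntri = (int)tris.size();
  std::vector<double> trival(ntri);
  for (int i = 0; i < ntri; i++) {
    Pt c; double r2;
    if (!tri_circum(P[tris[i][0]], P[tris[i][1]], P[tris[i][2]], c, r2))
      stop("degenerate triangle in Delaunay triangulation");
    bool gabriel = true;
    double minco = R_PosInf;
    for (size_t k = 0; k < tricof[i].size(); k++) {
      minco = std::min(minco, tetval[tricof[i][k].first]);
      if (dist2(P[tricof[i][k].second], c) < r2) gabriel = false;
    }
    trival[i] = gabriel ? r2 : minco;
  }

  // Edges from triangles.
  typedef std::array<int, 2> Edge;
  std::map<Edge, int> edid;
  std::vector<Edge> eds;
  std::vector<std::vector<std::pair<int, int> > > edcof; // (triangle, opp)
  for (int i = 0; i < ntri; i++) {
    for (int f = 0; f < 3; f++) {
      Edge e; int m = 0, opp = -1;
      for (int k = 0; k < 3; k++) {
        if (k == f) opp = tris[i][k]; else e[m++] = tris[i][k];
      }
      std::map<Edge, int>::iterator it = edid.find(e);
      int id;
      if (it == edid.end()) {
        id = (int)eds.size();
        edid[e] = id;
        eds.push_back(e);
        edcof.push_back(std::vector<std::pair<int, int> >());
      } else id = it->second;
      edcof[id].push_back(std::make_pair(i, opp));
    }
  }

  int ned = (int)eds.size();
  std::vector<double> edval(ned);
  for (int i = 0; i < ned; i++) {
    Pt c;
    for (int j = 0; j < 3; j++)
      c[j] = 0.5 * (P[eds[i][0]][j] + P[eds[i][1]][j]);
    double r2 = 0.25 * dist2(P[eds[i][0]], P[eds[i][1]]);
    bool gabriel = true;
    double minco = R_PosInf;
    for (size_t k = 0; k < edcof[i].size(); k++) {
      minco = std::min(minco, trival[edcof[i][k].first]);
      if (dist2(P[edcof[i][k].second], c) < r2) gabriel = false;
    }
    edval[i] = gabriel ? r2 : minco;
  }

  // Flattened simplex list: vertices (value 0), edges, triangles, tetrahedra.
  int m = n + ned + ntri + nt;
  IntegerVector dims(m);
  NumericVector values(m);
  std::vector<int> flat;
  flat.reserve(n + 2 * ned + 3 * ntri + 4 * nt);
  int s = 0;
  for (int i = 0; i < n; i++, s++) {
    dims[s] = 0; values[s] = 0.0; flat.push_back(i + 1);
  }
  for (int i = 0; i < ned; i++, s++) {
    dims[s] = 1; values[s] = edval[i];
    flat.push_back(eds[i][0] + 1); flat.push_back(eds[i][1] + 1);
  }
  for (int i = 0; i < ntri; i++, s++) {
    dims[s] = 2; values[s] = trival[i];
    for (int k = 0; k < 3; k++) flat.push_back(tris[i][k] + 1);
  }
  for (int t = 0; t < nt; t++, s++) {
    dims[s] = 3; values[s] = tetval[t];
    for (int k = 0; k < 4; k++) flat.push_back(tetra(t, k));
  }
  return List::create(_["dims"] = dims, _["values"] = values,
                      _["verts"] = IntegerVector(flat.begin(), flat.end()));
}

// Vietoris-Rips complex up to maxdim with the diameter convention.
// [[Rcpp::export]]
List vr_complex_cpp(NumericMatrix pts, int maxdim, double threshold) {
  int n = pts.nrow();
  std::vector<Pt> P(n);
  for (int i = 0; i < n; i++)
    for (int j = 0; j < 3; j++) P[i][j] = pts(i, j);
  std::vector<double> D(n * n, 0.0);
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++)
      D[i * n + j] = D[j * n + i] = std::sqrt(dist2(P[i], P[j]));

  std::vector<int> dims;
  std::vector<double> values;
  std::vector<int> flat;
  for (int i = 0; i < n; i++) {
    dims.push_back(0); values.push_back(0.0); flat.push_back(i + 1);
  }
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++)
      if (D[i * n + j] <= threshold) {
        dims.push_back(1); values.push_back(D[i * n + j]);
        flat.push_back(i + 1); flat.push_back(j + 1);
      }
  if (maxdim >= 2) {
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) {
        if (D[i * n + j] > threshold) continue;
        for (int k = j + 1; k < n; k++) {
          double v = std::max(D[i * n + j],
                              std::max(D[i * n + k], D[j * n + k]));
          if (v > threshold) continue;
          dims.push_back(2); values.push_back(v);
          flat.push_back(i + 1); flat.push_back(j + 1); flat.push_back(k + 1);
        }
      }
  }
  if (maxdim >= 3) {
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) {
        if (D[i * n + j] > threshold) continue;
        for (int k = j + 1; k < n; k++) {
          double v3 = std::max(D[i * n + j],
                               std::max(D[i * n + k], D[j * n + k]));
          if (v3 > threshold) continue;
          for (int l = k + 1; l < n; l++) {
            double v = std::max(v3, std::max(D[i * n + l],
                       std::max(D[j * n + l], D[k * n + l])));
            if (v > threshold) continue;
            dims.push_back(3); values.push_back(v);
            flat.push_back(i + 1); flat.push_back(j + 1);
            flat.push_back(k + 1); flat.push_back(l + 1);
          }
        }
      }
  }
  return List::create(_["dims"] = IntegerVector(dims.begin(), dims.end()),
                      _["values"] = NumericVector(values.begin(), values.end()),
                      _["verts"] = IntegerVector(flat.begin(), flat.end()));
}
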