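// Core geometry for trait-space functional diversity:
//  - 3-D convex hull volume (incremental algorithm)
//  - 3-D alpha-complex volume (Delaunay tetrahedra with circumradius <= alpha)
//  - Euclidean minimum spanning tree (Prim, deterministic tie-break)
//  - abundance-weighted functional evenness (FEve)
//  - the circular moving-window map loop gluing these together
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double nrm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;
  Vec3 n;       // outward normal (not normalized)
  double off;   // dot(n, vertex a)
  bool alive;
};

double bbox_diag(const std::vector<Vec3>& P) {
  double lo[3] = {P[0].x, P[0].y, P[0].z};
  double hi[3] = {P[0].x, P[0].y, P[0].z};
  for (const Vec3& p : P) {
    lo[0] = std::min(lo[0], p.x); hi[0] = std::max(hi[0], p.x);
    lo[1] = std::min(lo[1], p.y); hi[1] = std::max(hi[1], p.y);
    lo[2] = std::min(lo[2], p.z); hi[2] = std::max(hi[2], p.z);
  }
  double dx = hi[0] - lo[0], dy = hi[1] - lo[1], dz = hi[2] - lo[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Volume of the convex hull of P; 0 for degenerate (coplanar or fewer than
// 4 distinct) inputs. Incremental construction with horizon repair.
double hull_volume_impl(const std::vector<Vec3>& P) {
  const int n = static_cast<int>(P.size());
  if (n < 4) return 0.0;
  const double diag = bbox_diag(P);
  if (diag <= 0.0) return 0.0;
  const double tol = 1e-12 * diag;

  // initial simplex: far point, widest triangle, farthest-from-plane point
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = tol;
  for (int i = 1; i < n; ++i) {
    double d = nrm(sub(P[i], P[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (i1 < 0) return 0.0;
  best = tol * diag;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double a = nrm(cross(sub(P[i1], P[i0]), sub(P[i], P[i0])));
    if (a > best) { best = a; i2 = i; }
  }
  if (i2 < 0) return 0.0;
  Vec3 n0 = cross(sub(P[i1], P[i0]), sub(P[i2], P[i0]));
  best = tol * nrm(n0);
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double d = std::fabs(dot(n0, sub(P[i], P[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) return 0.0;

  Vec3 m{(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
         (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
         (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Face> faces;
  faces.reserve(8 * n);
  auto add_face = [&](int a, int b, int c) {
    Face f;
    f.a = a; f.b = b; f.c = c;
    f.n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
    f.off = dot(f.n, P[a]);
    if (dot(f.n, m) - f.off > 0) {  // orient outward from interior point m
      std::swap(f.b, f.c);
      f.n = cross(sub(P[f.b], P[f.a]), sub(P[f.c], P[f.a]));
      f.off = dot(f.n, P[f.a]);
    }
    f.alive = true;
    faces.push_back(f);
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  std::vector<int> visible;
  std::vector<std::pair<int, int> > edges;
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    visible.clear();
    for (int f = 0; f < static_cast<int>(faces.size()); ++f) {
      if (!faces[f].alive) continue;
      double d = dot(faces[f].n, P[p]) - faces[f].off;
      if (d > tol * (nrm(faces[f].n) + 1e-300)) visible.push_back(f);
    }
    if (visible.empty()) continue;
    edges.clear();
    for (int f : visible) {
      edges.push_back(std::make_pair(faces[f].a, faces[f].b));
      edges.push_back(std::make_pair(faces[f].b, faces[f].c));
      edges.push_back(std::make_pair(faces[f].c, faces[f].a));
      faces[f].alive = false;
    }
    for (const std::pair<int, int>& e : edges) {
      bool horizon = true;
      for (const std::pair<int, int>& r : edges) {
        if (r.first == e.second && r.second == e.first) { horizon = false; break; }
      }
      if (horizon) add_face(e.first, e.second, p);
    }
  }

  double vol = 0.0;
  for (const Face& f : faces) {
    if (!f.alive) continue;
    Vec3 a = sub(P[f.a], m), b = sub(P[f.b], m), c = sub(P[f.c], m);
    vol += dot(a, cross(b, c));
  }
  vol /= 6.0;
  return vol > 0.0 ? vol : 0.0;
}

// Circumcenter/radius of tetrahedron (A,B,C,D); returns radius, or -1 when
// the tetrahedron is (numerically) flat.
double circumsphere(const Vec3& A, const Vec3& B, const Vec3& C,
                    const Vec3& D, double scale, Vec3& center) {
  Vec3 u = sub(B, A), v = sub(C, A), w = sub(D, A);
  double det = dot(u, cross(v, w));
  if (std::fabs(det) < 1e-14 * scale * scale * scale) return -1.0;
  double ru = 0.5 * dot(u, u), rv = 0.5 * dot(v, v), rw = 0.5 * dot(w, w);
  // Solve [u; v; w] x = (ru, rv, rw) by Cramer's rule.
  Vec3 vxw = cross(v, w), wxu = cross(w, u), uxv = cross(u, v);
  Vec3 x{(ru * vxw.x + rv * wxu.x + rw * uxv.x) / det,
         (ru * vxw.y + rv * wxu.y + rw * uxv.y) / det,
         (ru * vxw.z + rv * wxu.z + rw * uxv.z) / det};
  center = Vec3{A.x + x.x, A.y + x.y, A.z + x.z};
  return nrm(x);
}

// Volume of the alpha complex: sum of volumes of Delaunay tetrahedra
// (empty circumsphere, brute force) whose circumradius is <= alpha.
double alpha_volume_impl(const std::vector<Vec3>& P, double alpha) {
  const int n = static_cast<int>(P.size());
  if (n < 4) return 0.0;
  const double diag = bbox_diag(P);
  if (diag <= 0.0) return 0.0;
  const double rtol = 1e-9 * diag;
  double vol = 0.0;
  Vec3 c;
  for (int i = 0; i < n - 3; ++i)
    for (int j = i + 1; j < n - 2; ++j)
      for (int k = j + 1; k < n - 1; ++k)
        for (int l = k + 1; l < n; ++l) {
          double r = circumsphere(P[i], P[j], P[k], P[l], diag, c);
          if (r < 0.0 || r > alpha) continue;
          bool empty = true;
          for (int q = 0; q < n; ++q) {
            if (q == i || q == j || q == k || q == l) continue;
            if (nrm(sub(P[q], c)) < r - rtol) { empty = false; break; }
          }
          if (!empty) continue;
          Vec3 u = sub(P[j], P[i]), v = sub(P[k], P[i]), w = sub(P[l], P[i]);
          vol += std::fabs(dot(u, cross(v, w))) / 6.0;
        }
  return vol;
}

// Prim's MST on the complete Euclidean graph. Deterministic: vertices are
// scanned in index order and strict improvement is required, so ties resolve
// to the lexicographically smallest (parent, child) pair.
void mst_impl(const std::vector<Vec3>& P, std::vector<int>& from,
              std::vector<int>& to, std::vector<double>& len) {
  const int n = static_cast<int>(P.size());
  from.clear(); to.clear(); len.clear();
  if (n < 2) return;
  std::vector<bool> in_tree(n, false);
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::vector<int> parent(n, -1);
  in_tree[0] = true;
  for (int j = 1; j < n; ++j) {
    dist[j] = nrm(sub(P[j], P[0]));
    parent[j] = 0;
  }
  for (int it = 1; it < n; ++it) {
    int best = -1;
    double bd = std::numeric_limits<double>::infinity();
    for (int j = 0; j < n; ++j)
      if (!in_tree[j] && dist[j] < bd) { bd = dist[j]; best = j; }
    in_tree[best] = true;
    from.push_back(parent[best]);
    to.push_back(best);
    len.push_back(bd);
    for (int j = 0; j < n; ++j) {
      if (in_tree[j]) continue;
      double d = nrm(sub(P[j], P[best]));
      if (d < dist[j]) { dist[j] = d; parent[j] = best; }
    }
  }
}

// Villeger-style FEve from MST branch lengths and abundances w (w > 0).
// Returns NA when the tree has zero total weighted length (coincident
// points) or fewer than 3 vertices.
double feve_impl(const std::vector<Vec3>& P, const std::vector<double>& w) {
  const int S = static_cast<int>(P.size());
  if (S < 3) return NA_REAL;
  std::vector<int> from, to;
  std::vector<double> len;
  mst_impl(P, from, to, len);
  const int m = static_cast<int>(len.size());
  double tot = 0.0;
  std::vector<double> ew(m);
  for (int l = 0; l < m; ++l) {
    ew[l] = len[l] / (w[from[l]] + w[to[l]]);
    tot += ew[l];
  }
  if (tot <= 0.0) return NA_REAL;
  const double thr = 1.0 / (S - 1.0);
  double acc = 0.0;
  for (int l = 0; l < m; ++l) acc += std::min(ew[l] / tot, thr);
  return (acc - thr) / (1.0 - thr);
}

double mean_mst_edge(const std::vector<Vec3>& P) {
  std::vector<int> from, to;
  std::vector<double> len;
  mst_impl(P, from, to, len);
  if (len.empty()) return 0.0;
  double s = 0.0;
  for (double d : len) s += d;
  return s / len.size();
}

std::vector<Vec3> as_points(const NumericMatrix& pts) {
  std::vector<Vec3> P(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    P[i] = Vec3{pts(i, 0), pts(i, 1), pts(i, 2)};
  return P;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_hull_volume")]]
double cpp_hull_volume(NumericMatrix pts) {
  if (pts.ncol() != 3) stop("points must be an N x 3 matrix");
  return hull_volume_impl(as_points(pts));
}

// [[Rcpp::export(name = ".cpp_alpha_volume")]]
double cpp_alpha_volume(NumericMatrix pts, double alpha) {
  if (pts.ncol() != 3) stop("points must be an N x 3 matrix");
  if (!std::isfinite(alpha)) return hull_volume_impl(as_points(pts));
  return alpha_volume_impl(as_points(pts), alpha);
}

// [[Rcpp::export(name = ".cpp_mst")]]
NumericMatrix cpp_mst(NumericMatrix pts) {
  if (pts.ncol() != 3) stop("points must be an N x 3 matrix");
  std::vector<Vec3> P = as_points(pts);
  std::vector<int> from, to;
  std::vector<double> len;
  mst_impl(P, from, to, len);
  NumericMatrix out(static_cast<int>(len.size()), 3);
  for (int l = 0; l < static_cast<int>(len.size()); ++l) {
    out(l, 0) = from[l] + 1;
    out(l, 1) = to[l] + 1;
    out(l, 2) = len[l];
  }
  colnames(out) = CharacterVector::create("from", "to", "length");
  return out;
}

// [[Rcpp::export(name = ".cpp_feve")]]
double cpp_feve(NumericMatrix pts, NumericVector w) {
  if (pts.ncol() != 3) stop("points must be an N x 3 matrix");
  if (w.size() != pts.nrow()) stop("weights must match the number of points");
  std::vector<double> wv(w.begin(), w.end());
  return feve_impl(as_points(pts), wv);
}

// Moving-window functional diversity. mode: 0 convex hull, 1 adaptive alpha
// (alpha = alpha_par * mean MST branch length per window), 2 fixed alpha.
// [[Rcpp::export(name = ".cpp_fd_map")]]
List cpp_fd_map(NumericMatrix t1, NumericMatrix t2, NumericMatrix t3,
                LogicalMatrix centers, NumericMatrix kernel, int mode,
                double alpha_par, int min_pts_ric, int min_pts_eve,
                double min_cover, bool use_kernel_weights) {
  const int nr = t1.nrow(), nc = t1.ncol();
  const int kr = kernel.nrow(), kc = kernel.ncol();
  if (kr % 2 == 0 || kc % 2 == 0) stop("kernel dimensions must be odd");
  if (kr > nr || kc > nc) stop("kernel larger than raster");
  const int hr = (kr - 1) / 2, hc = (kc - 1) / 2;
  double wtot = 0.0;
  for (int a = 0; a < kr; ++a)
    for (int b = 0; b < kc; ++b) wtot += kernel(a, b);

  NumericMatrix fric(nr, nc), feve(nr, nc), npts(nr, nc);
  std::fill(fric.begin(), fric.end(), NA_REAL);
  std::fill(feve.begin(), feve.end(), NA_REAL);
  std::fill(npts.begin(), npts.end(), NA_REAL);

  std::vector<Vec3> P;
  std::vector<double> W;
  for (int i = 0; i < nr; ++i) {
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
    for (int j = 0; j < nc; ++j) {
      if (centers(i, j) == NA_LOGICAL || !centers(i, j)) continue;
      P.clear();
      W.clear();
      double wvalid = 0.0;
      for (int a = 0; a < kr; ++a) {
        int ii = i + a - hr;
        if (ii < 0 || ii >= nr) continue;
        for (int b = 0; b < kc; ++b) {
          double kw = kernel(a, b);
          if (kw <= 0.0) continue;
          int jj = j + b - hc;
          if (jj < 0 || jj >= nc) continue;
          double v1 = t1(ii, jj), v2 = t2(ii, jj), v3 = t3(ii, jj);
          if (!std::isfinite(v1) || !std::isfinite(v2) || !std::isfinite(v3))
            continue;
          P.push_back(Vec3{v1, v2, v3});
          W.push_back(use_kernel_weights ? kw : 1.0);
          wvalid += kw;
        }
      }
      const int S = static_cast<int>(P.size());
      npts(i, j) = S;
      if (wvalid < min_cover * wtot) continue;
      if (S >= min_pts_eve) feve(i, j) = feve_impl(P, W);
      if (S >= min_pts_ric) {
        if (mode == 0) {
          fric(i, j) = hull_volume_impl(P);
        } else {
          double alpha = (mode == 1) ? alpha_par * mean_mst_edge(P) : alpha_par;
          fric(i, j) = alpha_volume_impl(P, alpha);
        }
      }
    }
  }
  return List::create(_["fric"] = fric, _["feve"] = feve, _["n_points"] = npts);
}
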