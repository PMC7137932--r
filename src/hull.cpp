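// Convex-hull primitives for functional-richness (FRic) computations and
// hull-constrained null models, plus batched null-model metric loops.
// Supports 1-3 embedding axes; the default axis rule caps the trait space at
// m = 3, so qhull-style general-dimension code is not needed.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <set>
#include <vector>

using namespace Rcpp;

namespace {

struct P2 {
  double x, y;
};

double cross2(const P2& o, const P2& a, const P2& b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

// Andrew's monotone chain; returns hull vertices in counter-clockwise order.
std::vector<P2> hull2(std::vector<P2> pts) {
  std::sort(pts.begin(), pts.end(), [](const P2& a, const P2& b) {
    return a.x < b.x || (a.x == b.x && a.y < b.y);
  });
  pts.erase(std::unique(pts.begin(), pts.end(), [](const P2& a, const P2& b) {
              return a.x == b.x && a.y == b.y;
            }),
            pts.end());
  const int n = static_cast<int>(pts.size());
  if (n < 3) return pts;
  std::vector<P2> h(2 * n);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    while (k >= 2 && cross2(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  for (int i = n - 2, t = k + 1; i >= 0; --i) {
    while (k >= t && cross2(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  h.resize(k - 1);
  return h;
}

double polygon_area(const std::vector<P2>& poly) {
  const int n = static_cast<int>(poly.size());
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0; i < n; ++i) {
    const P2& p = poly[i];
    const P2& q = poly[(i + 1) % n];
    a += p.x * q.y - q.x * p.y;
  }
  return 0.5 * std::fabs(a);
}

typedef std::array<double, 3> V3;

V3 sub3(const V3& a, const V3& b) { return V3{a[0] - b[0], a[1] - b[1], a[2] - b[2]}; }
double dot3(const V3& a, const V3& b) { return a[0] * b[0] + a[1] * b[1] + a[2] * b[2]; }
V3 cross3(const V3& a, const V3& b) {
  return V3{a[1] * b[2] - a[2] * b[1], a[2] * b[0] - a[0] * b[2],
            a[0] * b[1] - a[1] * b[0]};
}

double coord_scale(const NumericMatrix& pts) {
  double s = 0.0;
  for (int j = 0; j < pts.ncol(); ++j) {
    double mn = R_PosInf, mx = R_NegInf;
    for (int i = 0; i < pts.nrow(); ++i) {
      mn = std::min(mn, pts(i, j));
      mx = std::max(mx, pts(i, j));
    }
    s = std::max(s, mx - mn);
  }
  return s;
}

// One supporting facet: unit outward normal u with offset b; inside points
// satisfy dot(u, x) <= b (+ tolerance).
struct Facet {
  std::vector<double> u;
  double b;
};

// Enumerate supporting facets. degenerate is set when the point cloud has
// affine rank < m. Works for m in {1,2,3}.
std::vector<Facet> facets_of(const NumericMatrix& pts, bool& degenerate) {
  const int n = pts.nrow(), m = pts.ncol();
  const double scale = std::max(coord_scale(pts), 1e-300);
  const double tol = 1e-9 * scale;
  std::vector<Facet> out;
  degenerate = false;

  if (m == 1) {
    double mn = R_PosInf, mx = R_NegInf;
    for (int i = 0; i < n; ++i) {
      mn = std::min(mn, pts(i, 0));
      mx = std::max(mx, pts(i, 0));
    }
    if (mx - mn <= tol) { degenerate = true; return out; }
    out.push_back(Facet{{1.0}, mx});
    out.push_back(Facet{{-1.0}, -mn});
    return out;
  }

  if (m == 2) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const double ex = pts(j, 0) - pts(i, 0), ey = pts(j, 1) - pts(i, 1);
        const double len = std::sqrt(ex * ex + ey * ey);
        if (len <= tol) continue;
        double ux = ey / len, uy = -ex / len;  // one of the two normals
        double mn = R_PosInf, mx = R_NegInf;
        for (int l = 0; l < n; ++l) {
          const double d = ux * (pts(l, 0) - pts(i, 0)) + uy * (pts(l, 1) - pts(i, 1));
          mn = std::min(mn, d);
          mx = std::max(mx, d);
        }
        if (mn >= -tol && mx <= tol) { degenerate = true; out.clear(); return out; }
        if (mx <= tol) {
          out.push_back(Facet{{ux, uy}, ux * pts(i, 0) + uy * pts(i, 1)});
        } else if (mn >= -tol) {
          out.push_back(Facet{{-ux, -uy}, -(ux * pts(i, 0) + uy * pts(i, 1))});
        }
      }
    }
    if (out.empty()) degenerate = true;
    return out;
  }

  // m == 3
  std::vector<V3> P(n);
  for (int i = 0; i < n; ++i) P[i] = V3{pts(i, 0), pts(i, 1), pts(i, 2)};
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      for (int k = j + 1; k < n; ++k) {
        V3 nrm = cross3(sub3(P[j], P[i]), sub3(P[k], P[i]));
        const double nn = std::sqrt(dot3(nrm, nrm));
        if (nn <= tol * scale) continue;  // collinear triplet
        V3 u{nrm[0] / nn, nrm[1] / nn, nrm[2] / nn};
        double mn = R_PosInf, mx = R_NegInf;
        for (int l = 0; l < n; ++l) {
          const double d = dot3(u, sub3(P[l], P[i]));
          mn = std::min(mn, d);
          mx = std::max(mx, d);
        }
        if (mn >= -tol && mx <= tol) { degenerate = true; out.clear(); return out; }
        if (mx <= tol) {
          out.push_back(Facet{{u[0], u[1], u[2]}, dot3(u, P[i])});
        } else if (mn >= -tol) {
          out.push_back(Facet{{-u[0], -u[1], -u[2]}, -dot3(u, P[i])});
        }
      }
    }
  }
  if (out.empty()) degenerate = true;
  return out;
}

double volume_impl(const NumericMatrix& pts) {
  const int n = pts.nrow(), m = pts.ncol();
  const double scale = std::max(coord_scale(pts), 1e-300);
  const double tol = 1e-9 * scale;

  if (m == 1) {
    double mn = R_PosInf, mx = R_NegInf;
    for (int i = 0; i < n; ++i) {
      mn = std::min(mn, pts(i, 0));
      mx = std::max(mx, pts(i, 0));
    }
    return (mx - mn <= tol) ? NA_REAL : mx - mn;
  }

  if (m == 2) {
    std::vector<P2> v(n);
    for (int i = 0; i < n; ++i) v[i] = P2{pts(i, 0), pts(i, 1)};
    std::vector<P2> h = hull2(v);
    const double a = polygon_area(h);
    return (h.size() < 3 || a <= tol * scale) ? NA_REAL : a;
  }

  // m == 3: sum pyramids (facet polygon x apex at the cloud centroid).
  std::vector<V3> P(n);
  V3 C{0, 0, 0};
  for (int i = 0; i < n; ++i) {
    P[i] = V3{pts(i, 0), pts(i, 1), pts(i, 2)};
    for (int d = 0; d < 3; ++d) C[d] += P[i][d] / n;
  }
  std::set<std::vector<int>> seen;
  double vol = 0.0;
  bool any = false;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      for (int k = j + 1; k < n; ++k) {
        V3 nrm = cross3(sub3(P[j], P[i]), sub3(P[k], P[i]));
        const double nn = std::sqrt(dot3(nrm, nrm));
        if (nn <= tol * scale) continue;
        V3 u{nrm[0] / nn, nrm[1] / nn, nrm[2] / nn};
        double mn = R_PosInf, mx = R_NegInf;
        for (int l = 0; l < n; ++l) {
          const double d = dot3(u, sub3(P[l], P[i]));
          mn = std::min(mn, d);
          mx = std::max(mx, d);
        }
        if (mn >= -tol && mx <= tol) return NA_REAL;  // all coplanar
        if (!(mx <= tol) && !(mn >= -tol)) continue;  // not supporting
        if (mn >= -tol) u = V3{-u[0], -u[1], -u[2]};  // orient outward
        std::vector<int> onpl;
        for (int l = 0; l < n; ++l)
          if (std::fabs(dot3(u, sub3(P[l], P[i]))) <= tol) onpl.push_back(l);
        if (!seen.insert(onpl).second) continue;
        // facet polygon area in its own plane
        V3 e1 = sub3(P[j], P[i]);
        const double e1n = std::sqrt(dot3(e1, e1));
        e1 = V3{e1[0] / e1n, e1[1] / e1n, e1[2] / e1n};
        V3 e2 = cross3(u, e1);
        std::vector<P2> proj;
        proj.reserve(onpl.size());
        for (int idx : onpl) {
          V3 w = sub3(P[idx], P[i]);
          proj.push_back(P2{dot3(e1, w), dot3(e2, w)});
        }
        const double area = polygon_area(hull2(proj));
        const double h = dot3(u, sub3(P[i], C));  // apex height, >= 0
        vol += area * h / 3.0;
        any = true;
      }
    }
  }
  return any ? vol : NA_REAL;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".hull_volume_cpp")]]
double hull_volume_cpp(NumericMatrix pts) {
  if (pts.ncol() < 1 || pts.ncol() > 3)
    stop("convex hull volume supported for 1-3 dimensions, got %d", pts.ncol());
  if (pts.nrow() < pts.ncol() + 1) return NA_REAL;
  return volume_impl(pts);
}

// Membership against the convex hull of hull_pts. Returns NA for every query
// when the hull is degenerate (affine rank < m); the R wrapper then falls
// back to an affine-subspace test.
// [[Rcpp::export(name = ".in_hull_cpp")]]
LogicalVector in_hull_cpp(NumericMatrix hull_pts, NumericMatrix queries, double tol) {
  const int m = hull_pts.ncol();
  if (queries.ncol() != m) stop("query dimension mismatch");
  if (m < 1 || m > 3) stop("in_hull supported for 1-3 dimensions");
  bool degenerate = false;
  std::vector<Facet> fs = facets_of(hull_pts, degenerate);
  LogicalVector res(queries.nrow());
  if (degenerate) {
    std::fill(res.begin(), res.end(), NA_LOGICAL);
    return res;
  }
  const double scale = std::max(coord_scale(hull_pts), 1.0);
  const double slack = std::max(tol, 1e-12) * scale;
  for (int q = 0; q < queries.nrow(); ++q) {
    bool inside = true;
    for (const Facet& f : fs) {
      double d = -f.b;
      for (int j = 0; j < m; ++j) d += f.u[j] * queries(q, j);
      if (d > slack) { inside = false; break; }
    }
    res[q] = inside;
  }
  return res;
}

// Batched FRic over permuted communities: idx is n_perm x S, 1-based rows
// into coords. Returns hull volume per permutation (NA where degenerate).
// [[Rcpp::export(name = ".null_fric_cpp")]]
NumericVector null_fric_cpp(NumericMatrix coords, IntegerMatrix idx) {
  const int m = coords.ncol(), S = idx.ncol(), nperm = idx.nrow();
  NumericVector out(nperm);
  NumericMatrix sub(S, m);
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < S; ++i) {
      const int r = idx(p, i) - 1;
      for (int j = 0; j < m; ++j) sub(i, j) = coords(r, j);
    }
    out[p] = (S < m + 1) ? NA_REAL : volume_impl(sub);
  }
  return out;
}

// Batched mean nearest-neighbour distance on a precomputed distance matrix.
// [[Rcpp::export(name = ".null_mnnd_cpp")]]
NumericVector null_mnnd_cpp(NumericMatrix D, IntegerMatrix idx) {
  const int S = idx.ncol(), nperm = idx.nrow();
  NumericVector out(nperm);
  for (int p = 0; p < nperm; ++p) {
    if (S < 2) { out[p] = NA_REAL; continue; }
    double acc = 0.0;
    for (int i = 0; i < S; ++i) {
      double mn = R_PosInf;
      for (int j = 0; j < S; ++j) {
        if (i == j) continue;
        mn = std::min(mn, D(idx(p, i) - 1, idx(p, j) - 1));
      }
      acc += mn;
    }
    out[p] = acc / S;
  }
  return out;
}

// Exact two-sided permutation p-value for the Spearman correlation of two
// (mid)rank vectors, by enumeration of the distinct arrangements of ry.
// With ties, distinct sequences carry equal multiplicity, so the fraction
// over distinct sequences equals the fraction over all n! permutations.
// [[Rcpp::export(name = ".spearman_perm_p_cpp")]]
double spearman_perm_p_cpp(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  if (ry.size() != n) stop("length mismatch");
  std::vector<double> x(rx.begin(), rx.end()), y(ry.begin(), ry.end());
  double t_obs = 0.0, mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) {
    t_obs += x[i] * y[i];
    mx += x[i] / n;
    my += y[i] / n;
  }
  const double centre = n * mx * my;
  const double dev_obs = std::fabs(t_obs - centre);
  std::sort(y.begin(), y.end());
  long long total = 0, hits = 0;
  const double eps = 1e-9 * (std::fabs(centre) + 1.0);
  do {
    double t = 0.0;
    for (int i = 0; i < n; ++i) t += x[i] * y[i];
    ++total;
    if (std::fabs(t - centre) >= dev_obs - eps) ++hits;
  } while (std::next_permutation(y.begin(), y.end()));
  return static_cast<double>(hits) / static_cast<double>(total);
}
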