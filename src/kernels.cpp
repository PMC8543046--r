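// Geometry kernels: point-to-triangle-mesh distance with a BVH, ray-parity
// inside tests, triangle-triangle crossing audits, marching-tetrahedra
// clipping for the BCC lattice mesher, scaled-Jacobian quality, and the
// anisotropic Eikonal local solver.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <unordered_map>
#include <cstdint>
#include <limits>

using namespace Rcpp;

typedef std::array<double, 3> V3;

static inline V3 v3(double x, double y, double z) { V3 r = {x, y, z}; return r; }
static inline V3 sub(const V3& a, const V3& b) { return v3(a[0]-b[0], a[1]-b[1], a[2]-b[2]); }
static inline V3 add(const V3& a, const V3& b) { return v3(a[0]+b[0], a[1]+b[1], a[2]+b[2]); }
static inline V3 scl(const V3& a, double s) { return v3(a[0]*s, a[1]*s, a[2]*s); }
static inline double dot(const V3& a, const V3& b) { return a[0]*b[0]+a[1]*b[1]+a[2]*b[2]; }
static inline V3 cross(const V3& a, const V3& b) {
  return v3(a[1]*b[2]-a[2]*b[1], a[2]*b[0]-a[0]*b[2], a[0]*b[1]-a[1]*b[0]);
}
static inline double norm3(const V3& a) { return std::sqrt(dot(a, a)); }

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision Detection.
static V3 closest_on_tri(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return add(a, scl(ab, v));
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return add(a, scl(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return add(b, scl(sub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return add(a, add(scl(ab, v), scl(ac, w)));
}

struct BVHNode {
  double lo[3], hi[3];
  int left, right;    // -1 for leaf
  int start, count;   // triangle index range (leaf)
};

struct TriBVH {
  std::vector<V3> verts;
  std::vector<std::array<int,3> > tris;
  std::vector<int> order;       // triangle ids in BVH order
  std::vector<BVHNode> nodes;
  std::vector<V3> centroid;

  int build(int start, int count) {
    BVHNode nd;
    nd.lo[0] = nd.lo[1] = nd.lo[2] = std::numeric_limits<double>::infinity();
    nd.hi[0] = nd.hi[1] = nd.hi[2] = -std::numeric_limits<double>::infinity();
    for (int k = start; k < start + count; ++k) {
      const std::array<int,3>& t = tris[order[k]];
      for (int j = 0; j < 3; ++j) {
        const V3& p = verts[t[j]];
        for (int d = 0; d < 3; ++d) {
          nd.lo[d] = std::min(nd.lo[d], p[d]);
          nd.hi[d] = std::max(nd.hi[d], p[d]);
        }
      }
    }
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 8) {
      nodes[id].left = nodes[id].right = -1;
      nodes[id].start = start; nodes[id].count = count;
      return id;
    }
    // split along largest centroid extent
    double clo[3] = {1e300,1e300,1e300}, chi[3] = {-1e300,-1e300,-1e300};
    for (int k = start; k < start + count; ++k)
      for (int d = 0; d < 3; ++d) {
        double c = centroid[order[k]][d];
        clo[d] = std::min(clo[d], c); chi[d] = std::max(chi[d], c);
      }
    int axis = 0; double best = chi[0] - clo[0];
    for (int d = 1; d < 3; ++d) if (chi[d] - clo[d] > best) { best = chi[d] - clo[d]; axis = d; }
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count,
                     [&](int a, int b) { return centroid[a][axis] < centroid[b][axis]; });
    int l = build(start, mid - start);
    int r = build(mid, start + count - mid);
    nodes[id].left = l; nodes[id].right = r;
    nodes[id].start = start; nodes[id].count = count;
    return id;
  }

  void init(const NumericMatrix& V, const IntegerMatrix& F) {
    int nv = V.nrow(), nf = F.nrow();
    verts.resize(nv);
    for (int i = 0; i < nv; ++i) verts[i] = v3(V(i,0), V(i,1), V(i,2));
    tris.resize(nf);
    centroid.resize(nf);
    order.resize(nf);
    for (int i = 0; i < nf; ++i) {
      std::array<int,3> t = { F(i,0) - 1, F(i,1) - 1, F(i,2) - 1 };
      tris[i] = t;
      V3 c = scl(add(add(verts[t[0]], verts[t[1]]), verts[t[2]]), 1.0/3.0);
      centroid[i] = c;
      order[i] = i;
    }
    nodes.reserve(2 * nf);
    if (nf > 0) build(0, nf);
  }

  static double box_dist2(const BVHNode& n, const V3& p) {
    double d2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      double v = 0.0;
      if (p[d] < n.lo[d]) v = n.lo[d] - p[d];
      else if (p[d] > n.hi[d]) v = p[d] - n.hi[d];
      d2 += v * v;
    }
    return d2;
  }

  // nearest point on mesh; returns squared distance, fills q and tri id
  double nearest(const V3& p, V3& q, int& tri) const {
    double best = std::numeric_limits<double>::infinity();
    tri = -1;
    std::vector<int> stack;
    stack.reserve(64);
    stack.push_back(0);
    while (!stack.empty()) {
      int id = stack.back(); stack.pop_back();
      const BVHNode& nd = nodes[id];
      if (box_dist2(nd, p) >= best) continue;
      if (nd.left < 0) {
        for (int k = nd.start; k < nd.start + nd.count; ++k) {
          const std::array<int,3>& t = tris[order[k]];
          V3 c = closest_on_tri(p, verts[t[0]], verts[t[1]], verts[t[2]]);
          V3 d = sub(p, c);
          double d2 = dot(d, d);
          if (d2 < best) { best = d2; q = c; tri = order[k]; }
        }
      } else {
        double dl = box_dist2(nodes[nd.left], p), dr = box_dist2(nodes[nd.right], p);
        if (dl < dr) { stack.push_back(nd.right); stack.push_back(nd.left); }
        else { stack.push_back(nd.left); stack.push_back(nd.right); }
      }
    }
    return best;
  }

  static bool ray_box(const BVHNode& n, const V3& o, const V3& inv) {
    double t0 = 0.0, t1 = std::numeric_limits<double>::infinity();
    for (int d = 0; d < 3; ++d) {
      double a = (n.lo[d] - o[d]) * inv[d];
      double b = (n.hi[d] - o[d]) * inv[d];
      if (a > b) std::swap(a, b);
      t0 = std::max(t0, a); t1 = std::min(t1, b);
      if (t0 > t1) return false;
    }
    return true;
  }

  // ray-triangle, Moller-Trumbore; status: 0 miss, 1 hit, 2 ambiguous
  static int ray_tri(const V3& o, const V3& dir, const V3& a, const V3& b, const V3& c,
                     double eps) {
    V3 e1 = sub(b, a), e2 = sub(c, a);
    V3 pv = cross(dir, e2);
    double det = dot(e1, pv);
    double scale = norm3(e1) * norm3(e2);
    if (std::fabs(det) < 1e-12 * scale) return 0;  // parallel: treat as miss
    double inv = 1.0 / det;
    V3 tv = sub(o, a);
    double u = dot(tv, pv) * inv;
    V3 qv = cross(tv, e1);
    double vv = dot(dir, qv) * inv;
    double t = dot(e2, qv) * inv;
    if (u < -eps || vv < -eps || u + vv > 1.0 + eps || t < -eps) return 0;
    if (u < eps || vv < eps || u + vv > 1.0 - eps || t < eps) return 2;
    return 1;
  }

  // parity inside test; deterministic direction fallbacks
  int inside(const V3& p) const {
    static const double DIRS[8][3] = {
      {0.5730237, 0.6340112, 0.5192333}, {-0.3612501, 0.8312345, 0.4223311},
      {0.7071068, -0.4082483, 0.5773503}, {0.1234567, 0.4567891, -0.8809713},
      {-0.5773503, -0.5773503, 0.5773503}, {0.9128709, 0.2182179, 0.3450328},
      {0.2672612, -0.5345225, -0.8017837}, {-0.4850713, 0.7276069, -0.4850713}
    };
    for (int attempt = 0; attempt < 8; ++attempt) {
      V3 dir = v3(DIRS[attempt][0], DIRS[attempt][1], DIRS[attempt][2]);
      V3 inv = v3(1.0/dir[0], 1.0/dir[1], 1.0/dir[2]);
      int count = 0;
      bool ambiguous = false;
      std::vector<int> stack;
      stack.push_back(0);
      while (!stack.empty() && !ambiguous) {
        int id = stack.back(); stack.pop_back();
        const BVHNode& nd = nodes[id];
        if (!ray_box(nd, p, inv)) continue;
        if (nd.left < 0) {
          for (int k = nd.start; k < nd.start + nd.count; ++k) {
            const std::array<int,3>& t = tris[order[k]];
            int st = ray_tri(p, dir, verts[t[0]], verts[t[1]], verts[t[2]], 1e-9);
            if (st == 2) { ambiguous = true; break; }
            count += st;
          }
        } else {
          stack.push_back(nd.left); stack.push_back(nd.right);
        }
      }
      if (!ambiguous) return count % 2;
    }
    return 0;  // pathological; report outside
  }
};

// [[Rcpp::export]]
SEXP cpp_bvh_build(NumericMatrix V, IntegerMatrix F) {
  XPtr<TriBVH> p(new TriBVH(), true);
  p->init(V, F);
  return p;
}

// [[Rcpp::export]]
List cpp_bvh_query(SEXP bvh_, NumericMatrix P) {
  XPtr<TriBVH> bvh(bvh_);
  int n = P.nrow();
  NumericVector dist(n);
  NumericMatrix nearest(n, 3);
  IntegerVector tri(n);
  for (int i = 0; i < n; ++i) {
    V3 p = v3(P(i,0), P(i,1), P(i,2)), q;
    int t;
    double d2 = bvh->nearest(p, q, t);
    dist[i] = std::sqrt(d2);
    nearest(i,0) = q[0]; nearest(i,1) = q[1]; nearest(i,2) = q[2];
    tri[i] = t + 1;
  }
  return List::create(_["distance"] = dist, _["nearest"] = nearest, _["triangle"] = tri);
}

// [[Rcpp::export]]
LogicalVector cpp_bvh_inside(SEXP bvh_, NumericMatrix P) {
  XPtr<TriBVH> bvh(bvh_);
  int n = P.nrow();
  LogicalVector res(n);
  for (int i = 0; i < n; ++i) res[i] = bvh->inside(v3(P(i,0), P(i,1), P(i,2))) == 1;
  return res;
}

// Brute-force point-to-mesh distance (oracle / small meshes).
// [[Rcpp::export]]
NumericVector cpp_point_mesh_bruteforce(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int n = P.nrow(), m = F.nrow();
  std::vector<V3> verts(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) verts[i] = v3(V(i,0), V(i,1), V(i,2));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    V3 p = v3(P(i,0), P(i,1), P(i,2));
    double best = std::numeric_limits<double>::infinity();
    for (int k = 0; k < m; ++k) {
      V3 c = closest_on_tri(p, verts[F(k,0)-1], verts[F(k,1)-1], verts[F(k,2)-1]);
      V3 d = sub(p, c);
      best = std::min(best, dot(d, d));
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------- triangle-triangle crossing audit ------------------------

// Moller 1997 interval overlap test; coplanar pairs are not counted as
// crossings (contact without straddling is tolerated by the audits).
static bool tri_tri_cross(const V3& a0, const V3& a1, const V3& a2,
                          const V3& b0, const V3& b1, const V3& b2) {
  V3 n2 = cross(sub(b1, b0), sub(b2, b0));
  double d2 = -dot(n2, b0);
  double da0 = dot(n2, a0) + d2, da1 = dot(n2, a1) + d2, da2 = dot(n2, a2) + d2;
  double eps2 = 1e-12 * dot(n2, n2);
  if ((da0 > 0 && da1 > 0 && da2 > 0) || (da0 < 0 && da1 < 0 && da2 < 0)) return false;
  V3 n1 = cross(sub(a1, a0), sub(a2, a0));
  double d1 = -dot(n1, a0);
  double db0 = dot(n1, b0) + d1, db1 = dot(n1, b1) + d1, db2 = dot(n1, b2) + d1;
  if ((db0 > 0 && db1 > 0 && db2 > 0) || (db0 < 0 && db1 < 0 && db2 < 0)) return false;
  if (std::fabs(da0) < eps2 && std::fabs(da1) < eps2 && std::fabs(da2) < eps2) return false;
  V3 D = cross(n1, n2);
  int axis = 0;
  double m = std::fabs(D[0]);
  if (std::fabs(D[1]) > m) { m = std::fabs(D[1]); axis = 1; }
  if (std::fabs(D[2]) > m) { axis = 2; }
  double pa0 = a0[axis], pa1 = a1[axis], pa2 = a2[axis];
  double pb0 = b0[axis], pb1 = b1[axis], pb2 = b2[axis];
  // interval of triangle A on the intersection line
  auto interval = [](double p0, double p1, double p2, double s0, double s1, double s2,
                     double& t0, double& t1) -> bool {
    // edges crossing the plane of the other triangle
    double ts[3]; int nt = 0;
    double ps[3] = {p0, p1, p2}, ss[3] = {s0, s1, s2};
    for (int i = 0; i < 3; ++i) {
      int j = (i + 1) % 3;
      if ((ss[i] > 0 && ss[j] < 0) || (ss[i] < 0 && ss[j] > 0)) {
        double f = ss[i] / (ss[i] - ss[j]);
        ts[nt++] = ps[i] + f * (ps[j] - ps[i]);
      } else if (ss[i] == 0) {
        ts[nt++] = ps[i];
      }
    }
    if (nt < 2) return false;
    t0 = *std::min_element(ts, ts + nt);
    t1 = *std::max_element(ts, ts + nt);
    return true;
  };
  double s0, s1, t0, t1;
  if (!interval(pa0, pa1, pa2, da0, da1, da2, s0, s1)) return false;
  if (!interval(pb0, pb1, pb2, db0, db1, db2, t0, t1)) return false;
  double lo = std::max(s0, t0), hi = std::min(s1, t1);
  return hi - lo > 1e-10;
}

// [[Rcpp::export]]
int cpp_tri_tri_crossings(NumericMatrix V1, IntegerMatrix F1,
                          NumericMatrix V2, IntegerMatrix F2) {
  TriBVH bvh;
  bvh.init(V2, F2);
  std::vector<V3> v1(V1.nrow());
  for (int i = 0; i < V1.nrow(); ++i) v1[i] = v3(V1(i,0), V1(i,1), V1(i,2));
  int count = 0;
  for (int k = 0; k < F1.nrow(); ++k) {
    V3 a0 = v1[F1(k,0)-1], a1 = v1[F1(k,1)-1], a2 = v1[F1(k,2)-1];
    BVHNode box;
    for (int d = 0; d < 3; ++d) {
      box.lo[d] = std::min(a0[d], std::min(a1[d], a2[d])) - 1e-9;
      box.hi[d] = std::max(a0[d], std::max(a1[d], a2[d])) + 1e-9;
    }
    std::vector<int> stack;
    stack.push_back(0);
    while (!stack.empty()) {
      int id = stack.back(); stack.pop_back();
      const BVHNode& nd = bvh.nodes[id];
      bool overlap = true;
      for (int d = 0; d < 3; ++d)
        if (nd.lo[d] > box.hi[d] || nd.hi[d] < box.lo[d]) { overlap = false; break; }
      if (!overlap) continue;
      if (nd.left < 0) {
        for (int kk = nd.start; kk < nd.start + nd.count; ++kk) {
          const std::array<int,3>& t = bvh.tris[bvh.order[kk]];
          if (tri_tri_cross(a0, a1, a2, bvh.verts[t[0]], bvh.verts[t[1]], bvh.verts[t[2]]))
            ++count;
        }
      } else {
        stack.push_back(nd.left); stack.push_back(nd.right);
      }
    }
  }
  return count;
}

// ---------------- scaled Jacobian (Knupp) ---------------------------------

static double knupp_one(const V3& p0, const V3& p1, const V3& p2, const V3& p3) {
  const V3* P[4] = {&p0, &p1, &p2, &p3};
  double worst = 1.0;
  for (int v = 0; v < 4; ++v) {
    V3 e[3];
    int k = 0;
    for (int j = 0; j < 4; ++j) if (j != v) e[k++] = sub(*P[j], *P[v]);
    double det = dot(e[0], cross(e[1], e[2]));
    double l = norm3(e[0]) * norm3(e[1]) * norm3(e[2]);
    double s = (l > 0.0) ? std::sqrt(2.0) * std::fabs(det) / l : 0.0;
    if (s < worst) worst = s;
  }
  return std::min(1.0, std::max(0.0, worst));
}

// [[Rcpp::export]]
NumericVector cpp_knupp(NumericMatrix V, IntegerMatrix T) {
  int m = T.nrow();
  std::vector<V3> verts(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) verts[i] = v3(V(i,0), V(i,1), V(i,2));
  NumericVector out(m);
  for (int k = 0; k < m; ++k)
    out[k] = knupp_one(verts[T(k,0)-1], verts[T(k,1)-1], verts[T(k,2)-1], verts[T(k,3)-1]);
  return out;
}

// ---------------- marching-tetrahedra clipping ----------------------------

// Clip a tetra complex against sdf <= 0 (vertices with sdf == 0 lie on the
// surface). Cut points are keyed per global edge so shared faces agree; quads
// are split by the diagonal through their smallest global vertex id.
struct ClipBuilder {
  std::vector<V3> verts;
  std::vector<double> sdf;
  std::vector<std::array<int,4> > out;
  std::unordered_map<uint64_t, int> edge_cut;

  int cut(int a, int b) {
    if (sdf[a] == 0.0) return a;
    if (sdf[b] == 0.0) return b;
    uint64_t key = a < b ? ((uint64_t)a << 32) | (uint32_t)b
                         : ((uint64_t)b << 32) | (uint32_t)a;
    auto it = edge_cut.find(key);
    if (it != edge_cut.end()) return it->second;
    double t = sdf[a] / (sdf[a] - sdf[b]);
    V3 p = add(verts[a], scl(sub(verts[b], verts[a]), t));
    int id = (int)verts.size();
    verts.push_back(p);
    sdf.push_back(0.0);
    edge_cut[key] = id;
    return id;
  }

  void emit(int a, int b, int c, int d) {
    if (a == b || a == c || a == d || b == c || b == d || c == d) return;
    V3 e1 = sub(verts[b], verts[a]), e2 = sub(verts[c], verts[a]), e3 = sub(verts[d], verts[a]);
    double vol = dot(e1, cross(e2, e3));
    if (std::fabs(vol) < 1e-14) return;
    if (vol < 0) std::swap(c, d);
    std::array<int,4> t = {a, b, c, d};
    out.push_back(t);
  }

  // prism bottom (b0,b1,b2), top (t0,t1,t2); quads between column pairs.
  // fixed[k] for quad between columns (k, k+1 mod 3): -1 free, otherwise the
  // vertex id the prescribed diagonal must contain (bottom or top endpoint).
  void prism(int b[3], int t[3], int forced_diag_vertex[3]) {
    // zero-volume prism (all cuts snapped back onto the inside triangle):
    // the region degenerates to a face, nothing to emit
    {
      int bs[3] = {b[0], b[1], b[2]}, ts[3] = {t[0], t[1], t[2]};
      std::sort(bs, bs + 3);
      std::sort(ts, ts + 3);
      if (bs[0] == ts[0] && bs[1] == ts[1] && bs[2] == ts[2]) return;
    }
    // quad k has corners b[k], b[k1], t[k1], t[k]  (k1 = k+1 mod 3)
    // its two diagonals: (b[k], t[k1]) and (b[k1], t[k])
    // resolve prescribed diagonals by global-min rule where forced < 0
    int diag_from[3]; // the bottom-column index whose bottom vertex anchors the diagonal:
                      // diag k is (b[col], t[othercol])
    for (int k = 0; k < 3; ++k) {
      int k1 = (k + 1) % 3;
      if (forced_diag_vertex[k] >= 0) {
        int f = forced_diag_vertex[k];
        if (f == b[k] || f == t[k1]) diag_from[k] = 0;      // (b[k], t[k1])
        else diag_from[k] = 1;                              // (b[k1], t[k])
      } else {
        diag_from[k] = -1;
      }
    }
    // choose cone apex w: every prescribed diagonal of a quad incident to w
    // must contain w; free quads adapt.
    int cols_of_vertex[6][2] = { {2,0}, {0,1}, {1,2}, {2,0}, {0,1}, {1,2} };
    // vertex order: b0,b1,b2,t0,t1,t2 ; vertex b[k] touches quads (k-1) and k
    for (int wi = 0; wi < 6; ++wi) {
      bool isTop = wi >= 3;
      int col = wi % 3;
      int w = isTop ? t[col] : b[col];
      bool ok = true;
      int local_diag[3];
      for (int k = 0; k < 3; ++k) local_diag[k] = diag_from[k];
      for (int qi = 0; qi < 2; ++qi) {
        int q = cols_of_vertex[wi][qi];
        int k1 = (q + 1) % 3;
        // diagonal containing w on quad q?
        int need;
        if (!isTop) need = (col == q) ? 0 : 1;     // b[q] -> diag 0 ; b[q+1] -> diag 1
        else need = (col == k1) ? 0 : 1;           // t[q+1] -> diag 0 ; t[q] -> diag 1
        if (local_diag[q] < 0) local_diag[q] = need;
        else if (local_diag[q] != need) { ok = false; break; }
      }
      if (!ok) continue;
      // remaining free quad: any diagonal (take 0)
      for (int k = 0; k < 3; ++k) if (local_diag[k] < 0) local_diag[k] = 0;
      // cone from w over faces not containing w
      // faces: bottom tri, top tri, three quads (split per local_diag)
      if (isTop) emit(w, b[0], b[1], b[2]);
      else emit(w, t[0], t[2], t[1]);
      for (int k = 0; k < 3; ++k) {
        int k1 = (k + 1) % 3;
        // skip quads containing w
        if ((!isTop && (col == k || col == k1)) || (isTop && (col == k || col == k1))) continue;
        // quad corners: b[k], b[k1], t[k1], t[k]
        if (local_diag[k] == 0) { // diagonal (b[k], t[k1])
          emit(w, b[k], b[k1], t[k1]);
          emit(w, b[k], t[k1], t[k]);
        } else {                  // diagonal (b[k1], t[k])
          emit(w, b[k], b[k1], t[k]);
          emit(w, b[k1], t[k1], t[k]);
        }
      }
      return;
    }
    // cyclic prescribed diagonals: cone from centroid over all faces
    V3 c = v3(0,0,0);
    for (int k = 0; k < 3; ++k) c = add(c, add(verts[b[k]], verts[t[k]]));
    c = scl(c, 1.0/6.0);
    int cid = (int)verts.size();
    verts.push_back(c);
    sdf.push_back(-1.0);
    emit(cid, b[0], b[2], b[1]);
    emit(cid, t[0], t[1], t[2]);
    for (int k = 0; k < 3; ++k) {
      int k1 = (k + 1) % 3;
      int dg = diag_from[k] < 0 ? 0 : diag_from[k];
      if (dg == 0) {
        emit(cid, b[k], b[k1], t[k1]);
        emit(cid, b[k], t[k1], t[k]);
      } else {
        emit(cid, b[k], b[k1], t[k]);
        emit(cid, b[k1], t[k1], t[k]);
      }
    }
  }

  int quad_min_diag_vertex(int q0, int q1, int q2, int q3) {
    // corners in cyclic order; returns the smallest id corner (its diagonal)
    return std::min(std::min(q0, q1), std::min(q2, q3));
  }

  void clip_tet(int v0, int v1, int v2, int v3i) {
    int vs[4] = {v0, v1, v2, v3i};
    int in[4], nin = 0, nout = 0;
    for (int k = 0; k < 4; ++k) {
      in[k] = sdf[vs[k]] <= 0.0 ? 1 : 0;
      nin += in[k]; nout += 1 - in[k];
    }
    if (nin == 0) return;
    if (nout == 0) { emit(v0, v1, v2, v3i); return; }
    int ins[4], outs[4], ni = 0, no = 0;
    for (int k = 0; k < 4; ++k) (in[k] ? ins[ni++] : outs[no++]) = vs[k];
    if (nin == 1) {
      int p = ins[0];
      emit(p, cut(p, outs[0]), cut(p, outs[1]), cut(p, outs[2]));
    } else if (nin == 2) {
      int p = ins[0], q = ins[1], r = outs[0], s = outs[1];
      int cpr = cut(p, r), cps = cut(p, s), cqr = cut(q, r), cqs = cut(q, s);
      // prism bottom (p, cpr, cps), top (q, cqr, cqs)
      // quad 0: p,cpr | q,cqr  -> on tet face (p,q,r): prescribe min rule
      // quad 2: cps,p | cqs,q  -> on tet face (p,q,s): prescribe min rule
      // quad 1: cpr,cps | cqr,cqs -> cut surface: free
      int b[3] = {p, cpr, cps}, t[3] = {q, cqr, cqs};
      int forced[3];
      forced[0] = quad_min_diag_vertex(p, cpr, cqr, q);
      forced[1] = -1;
      forced[2] = quad_min_diag_vertex(cps, p, q, cqs);
      prism(b, t, forced);
    } else { // nin == 3
      int p = ins[0], q = ins[1], r = ins[2], s = outs[0];
      int cps = cut(p, s), cqs = cut(q, s), crs = cut(r, s);
      int b[3] = {p, q, r}, t[3] = {cps, cqs, crs};
      int forced[3];
      forced[0] = quad_min_diag_vertex(p, q, cqs, cps);
      forced[1] = quad_min_diag_vertex(q, r, crs, cqs);
      forced[2] = quad_min_diag_vertex(r, p, cps, crs);
      prism(b, t, forced);
    }
  }
};

// [[Rcpp::export]]
List cpp_clip_tets(NumericMatrix V, IntegerMatrix T, NumericVector sdf) {
  ClipBuilder cb;
  int nv = V.nrow();
  cb.verts.resize(nv);
  cb.sdf.resize(nv);
  for (int i = 0; i < nv; ++i) {
    cb.verts[i] = v3(V(i,0), V(i,1), V(i,2));
    cb.sdf[i] = sdf[i];
  }
  for (int k = 0; k < T.nrow(); ++k)
    cb.clip_tet(T(k,0)-1, T(k,1)-1, T(k,2)-1, T(k,3)-1);
  // compact vertices
  std::vector<int> remap(cb.verts.size(), -1);
  int nu = 0;
  for (size_t k = 0; k < cb.out.size(); ++k)
    for (int j = 0; j < 4; ++j) {
      int v = cb.out[k][j];
      if (remap[v] < 0) remap[v] = nu++;
    }
  NumericMatrix VO(nu, 3);
  for (size_t v = 0; v < remap.size(); ++v)
    if (remap[v] >= 0)
      for (int d = 0; d < 3; ++d) VO(remap[v], d) = cb.verts[v][d];
  IntegerMatrix TO(cb.out.size(), 4);
  for (size_t k = 0; k < cb.out.size(); ++k)
    for (int j = 0; j < 4; ++j) TO(k, j) = remap[cb.out[k][j]] + 1;
  return List::create(_["vertices"] = VO, _["tets"] = TO);
}

// ---------------- boundary faces of a tet complex -------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_tet_boundary(IntegerMatrix T, int nv) {
  // faces stored with sorted key; orientation so the face normal points out
  // of its tet (vertices ordered so that the fourth vertex is behind)
  std::unordered_map<uint64_t, std::pair<int,int> > count; // key -> (count, first index)
  int m = T.nrow();
  static const int FV[4][3] = { {1,2,3}, {0,3,2}, {0,1,3}, {0,2,1} };
  std::vector<std::array<int,3> > faces(4 * (size_t)m);
  for (int k = 0; k < m; ++k) {
    int v[4] = {T(k,0)-1, T(k,1)-1, T(k,2)-1, T(k,3)-1};
    for (int f = 0; f < 4; ++f) {
      std::array<int,3> fc = { v[FV[f][0]], v[FV[f][1]], v[FV[f][2]] };
      faces[4*(size_t)k + f] = fc;
      int s[3] = {fc[0], fc[1], fc[2]};
      std::sort(s, s + 3);
      uint64_t key = ((uint64_t)s[0] * (uint64_t)nv + (uint64_t)s[1]) * (uint64_t)nv + (uint64_t)s[2];
      auto it = count.find(key);
      if (it == count.end()) count[key] = std::make_pair(1, 4*k + f);
      else it->second.first += 1;
    }
  }
  std::vector<int> keep;
  for (auto& kv : count)
    if (kv.second.first == 1) keep.push_back(kv.second.second);
  std::sort(keep.begin(), keep.end());
  IntegerMatrix out(keep.size(), 3);
  for (size_t i = 0; i < keep.size(); ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = faces[keep[i]][j] + 1;
  return out;
}

// ---------------- tet mesh smoothing with quality guard --------------------

// [[Rcpp::export]]
NumericMatrix cpp_improve_tets(NumericMatrix V, IntegerMatrix T,
                               LogicalVector fixed, int iters) {
  int nv = V.nrow(), m = T.nrow();
  std::vector<V3> verts(nv);
  for (int i = 0; i < nv; ++i) verts[i] = v3(V(i,0), V(i,1), V(i,2));
  std::vector<std::array<int,4> > tets(m);
  std::vector<std::vector<int> > vtet(nv);
  for (int k = 0; k < m; ++k) {
    std::array<int,4> t = {T(k,0)-1, T(k,1)-1, T(k,2)-1, T(k,3)-1};
    tets[k] = t;
    for (int j = 0; j < 4; ++j) vtet[t[j]].push_back(k);
  }
  // vertex neighbours via tets
  std::vector<std::vector<int> > nbr(nv);
  for (int k = 0; k < m; ++k)
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        if (a != b) nbr[tets[k][a]].push_back(tets[k][b]);
  for (int i = 0; i < nv; ++i) {
    std::sort(nbr[i].begin(), nbr[i].end());
    nbr[i].erase(std::unique(nbr[i].begin(), nbr[i].end()), nbr[i].end());
  }
  auto min_quality = [&](int vi) {
    double q = 1.0;
    for (int k : vtet[vi]) {
      const std::array<int,4>& t = tets[k];
      double s = knupp_one(verts[t[0]], verts[t[1]], verts[t[2]], verts[t[3]]);
      if (s < q) q = s;
    }
    return q;
  };
  auto min_volume = [&](int vi) {
    double q = std::numeric_limits<double>::infinity();
    for (int k : vtet[vi]) {
      const std::array<int,4>& t = tets[k];
      V3 e1 = sub(verts[t[1]], verts[t[0]]);
      V3 e2 = sub(verts[t[2]], verts[t[0]]);
      V3 e3 = sub(verts[t[3]], verts[t[0]]);
      double vol = dot(e1, cross(e2, e3));
      if (vol < q) q = vol;
    }
    return q;
  };
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < nv; ++i) {
      if (fixed[i] || nbr[i].empty() || vtet[i].empty()) continue;
      double q0 = min_quality(i);
      if (q0 > 0.85) continue;
      V3 mean = v3(0, 0, 0);
      for (int j : nbr[i]) mean = add(mean, verts[j]);
      mean = scl(mean, 1.0 / nbr[i].size());
      V3 old = verts[i];
      // try full and damped moves; keep the best improvement
      double bestq = q0;
      V3 bestp = old;
      for (double w : {1.0, 0.5, 0.25}) {
        verts[i] = add(scl(old, 1.0 - w), scl(mean, w));
        if (min_volume(i) > 0) {
          double q = min_quality(i);
          if (q > bestq) { bestq = q; bestp = verts[i]; }
        }
      }
      verts[i] = bestp;
    }
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = verts[i][d];
  return out;
}

// ---------------- anisotropic Eikonal solver -------------------------------

// Local solve within one tet: arrival at d from the opposite face (a,b,c)
// with times ta,tb,tc under metric Q = M^{-1} (symmetric, rows of q).
static inline double qform(const double Q[6], const V3& x, const V3& y) {
  return Q[0]*x[0]*y[0] + Q[3]*x[1]*y[1] + Q[5]*x[2]*y[2]
       + Q[1]*(x[0]*y[1] + x[1]*y[0])
       + Q[2]*(x[0]*y[2] + x[2]*y[0])
       + Q[4]*(x[1]*y[2] + x[2]*y[1]);
}

static double edge_solve(const double Q[6], const V3& A, const V3& B, const V3& D,
                         double tA, double tB) {
  // min over lambda in [0,1] of (1-l) tA + l tB + ||D - (A + l (B-A))||_Q
  V3 u = sub(B, A), g = sub(D, A);
  double a = qform(Q, u, u), b = qform(Q, u, g), c = qform(Q, g, g);
  double dt = tB - tA;
  double best = std::numeric_limits<double>::infinity();
  auto eval = [&](double l) {
    V3 w = sub(g, scl(u, l));
    double s = std::sqrt(std::max(0.0, qform(Q, w, w)));
    double v = tA + l * dt + s;
    if (v < best) best = v;
  };
  eval(0.0); eval(1.0);
  double denom = 1.0 - dt * dt / a;
  if (a > 0 && denom > 1e-14) {
    double s2 = (c - b * b / a) / denom;
    if (s2 >= 0) {
      double s = std::sqrt(s2);
      double l = (b - dt * s) / a;
      if (l > 0.0 && l < 1.0) eval(l);
    }
  }
  return best;
}

static double face_solve(const double Q[6], const V3& A, const V3& B, const V3& C,
                         const V3& D, double tA, double tB, double tC) {
  V3 e1 = sub(A, C), e2 = sub(B, C), g = sub(D, C);
  double H11 = qform(Q, e1, e1), H12 = qform(Q, e1, e2), H22 = qform(Q, e2, e2);
  double b1 = qform(Q, e1, g), b2 = qform(Q, e2, g), c = qform(Q, g, g);
  double dt1 = tA - tC, dt2 = tB - tC;
  double det = H11 * H22 - H12 * H12;
  double best = std::numeric_limits<double>::infinity();
  if (det > 1e-14) {
    double i11 = H22 / det, i12 = -H12 / det, i22 = H11 / det;
    double l01 = i11 * b1 + i12 * b2, l02 = i12 * b1 + i22 * b2;   // H^-1 b
    double m1 = i11 * dt1 + i12 * dt2, m2 = i12 * dt1 + i22 * dt2; // H^-1 dt
    double denom = 1.0 - (dt1 * m1 + dt2 * m2);
    double num = c - (b1 * l01 + b2 * l02);
    if (denom > 1e-14 && num >= 0) {
      double s = std::sqrt(num / denom);
      double l1 = l01 - m1 * s, l2 = l02 - m2 * s;
      if (l1 > 0 && l2 > 0 && l1 + l2 < 1.0) {
        best = tC + l1 * dt1 + l2 * dt2 + s;
      }
    }
  }
  best = std::min(best, edge_solve(Q, A, B, D, tA, tB));
  best = std::min(best, edge_solve(Q, B, C, D, tB, tC));
  best = std::min(best, edge_solve(Q, A, C, D, tA, tC));
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_solve_eikonal(NumericMatrix V, IntegerMatrix T, NumericMatrix Qinv,
                                IntegerVector roots, NumericVector offsets,
                                double tol, int max_sweeps,
                                NumericVector init_times) {
  int nv = V.nrow(), m = T.nrow();
  std::vector<V3> verts(nv);
  for (int i = 0; i < nv; ++i) verts[i] = v3(V(i,0), V(i,1), V(i,2));
  std::vector<std::array<int,4> > tets(m);
  std::vector<std::vector<int> > vtet(nv);
  for (int k = 0; k < m; ++k) {
    std::array<int,4> t = {T(k,0)-1, T(k,1)-1, T(k,2)-1, T(k,3)-1};
    tets[k] = t;
    for (int j = 0; j < 4; ++j) vtet[t[j]].push_back(k);
  }
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> time(nv, INF), fixed_root(nv, INF);
  if (init_times.size() == nv)
    for (int i = 0; i < nv; ++i)
      if (R_finite(init_times[i])) time[i] = init_times[i];
  for (int r = 0; r < roots.size(); ++r) {
    int v = roots[r] - 1;
    fixed_root[v] = std::min(fixed_root[v], offsets[r]);
    time[v] = fixed_root[v];
  }
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double maxchg = 0.0;
    for (int i = 0; i < nv; ++i) {
      if (fixed_root[i] < INF) continue;
      double best = time[i];
      for (int k : vtet[i]) {
        const std::array<int,4>& t = tets[k];
        const double* Q = &Qinv(k, 0);
        double q[6] = {Q[0], Q[m], Q[2*m], Q[3*m], Q[4*m], Q[5*m]};
        int others[3], no = 0;
        for (int j = 0; j < 4; ++j) if (t[j] != i) others[no++] = t[j];
        double ta = time[others[0]], tb = time[others[1]], tc = time[others[2]];
        const V3& D = verts[i];
        double cand = INF;
        int nfinite = (ta < INF) + (tb < INF) + (tc < INF);
        if (nfinite == 0) continue;
        if (ta < INF && tb < INF && tc < INF) {
          cand = face_solve(q, verts[others[0]], verts[others[1]], verts[others[2]], D, ta, tb, tc);
        } else {
          // partial information: edge / vertex relaxations
          for (int a = 0; a < 3; ++a) {
            if (time[others[a]] >= INF) continue;
            V3 w = sub(D, verts[others[a]]);
            cand = std::min(cand, time[others[a]] + std::sqrt(std::max(0.0, qform(q, w, w))));
            for (int b = a + 1; b < 3; ++b) {
              if (time[others[b]] >= INF) continue;
              cand = std::min(cand, edge_solve(q, verts[others[a]], verts[others[b]], D,
                                               time[others[a]], time[others[b]]));
            }
          }
        }
        if (cand < best) best = cand;
      }
      if (best < time[i]) {
        double chg = time[i] - best;
        if (time[i] >= INF) chg = INF;
        time[i] = best;
        if (chg > maxchg) maxchg = chg;
      }
    }
    if (maxchg < tol) break;
  }
  NumericVector out(nv);
  for (int i = 0; i < nv; ++i) out[i] = time[i] < INF ? time[i] : NA_REAL;
  return out;
}

// Accessing Qinv row-wise above relies on column-major layout: &Qinv(k,0) with
// stride m. Kept explicit via the q[] copy.

// ---------------- bilinear sampling ----------------------------------------

// img: matrix (rows = i, cols = j); x = column coord, y = row coord, 0-based
// at pixel centres. Returns NA outside the grid.
// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericMatrix img, NumericVector x, NumericVector y) {
  int nr = img.nrow(), nc = img.ncol(), n = x.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double xj = x[k], yi = y[k];
    if (ISNAN(xj) || ISNAN(yi) || xj < 0 || yi < 0 || xj > nc - 1 || yi > nr - 1) {
      out[k] = NA_REAL;
      continue;
    }
    int j0 = (int)std::floor(xj), i0 = (int)std::floor(yi);
    if (j0 >= nc - 1) j0 = nc - 2;
    if (i0 >= nr - 1) i0 = nr - 2;
    if (nc == 1) j0 = 0;
    if (nr == 1) i0 = 0;
    double fx = xj - j0, fy = yi - i0;
    double v00 = img(i0, j0);
    double v01 = (nc > 1) ? img(i0, j0 + 1) : v00;
    double v10 = (nr > 1) ? img(i0 + 1, j0) : v00;
    double v11 = (nr > 1 && nc > 1) ? img(i0 + 1, j0 + 1) : v00;
    double va = ISNAN(v00) || ISNAN(v01) ? NA_REAL : v00 * (1 - fx) + v01 * fx;
    double vb = ISNAN(v10) || ISNAN(v11) ? NA_REAL : v10 * (1 - fx) + v11 * fx;
    out[k] = (ISNAN(va) || ISNAN(vb)) ? NA_REAL : va * (1 - fy) + vb * fy;
  }
  return out;
}

// ---------------- contour-crossing pair dissimilarity (hot path) -----------

// Greedy nearest-first matching of two sorted crossing-position vectors; the
// mean |ti - tj| over matched pairs. Mirrors the reference R implementation.
static void greedy_match(const std::vector<double>& a, const std::vector<double>& b,
                         double& sum, int& count) {
  size_t na = a.size(), nb = b.size();
  if (na == 0 || nb == 0) return;
  std::vector<char> ua(na, 0), ub(nb, 0);
  struct Cand { double d; int i, j; };
  std::vector<Cand> cands;
  cands.reserve(na * nb);
  for (size_t i = 0; i < na; ++i)
    for (size_t j = 0; j < nb; ++j) {
      Cand c = { std::fabs(a[i] - b[j]), (int)i, (int)j };
      cands.push_back(c);
    }
  std::stable_sort(cands.begin(), cands.end(), [](const Cand& x, const Cand& y) {
    if (x.d != y.d) return x.d < y.d;
    if (x.i != y.i) return x.i < y.i;
    return x.j < y.j;
  });
  for (const Cand& c : cands) {
    if (ua[c.i] || ub[c.j]) continue;
    ua[c.i] = ub[c.j] = 1;
    sum += c.d;
    ++count;
  }
}

// crossings of packed contours with a line (p0, d) in plane coordinates,
// appended per label (1..5)
static void contour_line_crossings(const NumericMatrix& pts, const IntegerVector& start,
                                   const IntegerVector& len, const IntegerVector& lab,
                                   const LogicalVector& closed,
                                   double p0x, double p0y, double dx, double dy,
                                   std::vector<double> ts[6]) {
  for (int c = 0; c < start.size(); ++c) {
    int s0 = start[c], n = len[c];
    int L = lab[c];
    int nseg = closed[c] ? n : n - 1;
    double prev_s = 0.0;
    for (int k = 0; k < nseg; ++k) {
      int ia = s0 + k;
      int ib = s0 + ((k + 1) % n);
      double ax = pts(ia, 0) - p0x, ay = pts(ia, 1) - p0y;
      double bx = pts(ib, 0) - p0x, by = pts(ib, 1) - p0y;
      double sa = ax * dy - ay * dx;
      double sb = bx * dy - by * dx;
      bool cross = (sa <= 0 && sb > 0) || (sa > 0 && sb <= 0);
      (void)prev_s;
      if (!cross) continue;
      double f = sa / (sa - sb);
      double qx = ax + f * (bx - ax);
      double qy = ay + f * (by - ay);
      ts[L].push_back(qx * dx + qy * dy);
    }
  }
}

// [[Rcpp::export]]
double cpp_contour_pair_E(NumericVector oi, NumericVector ui, NumericVector vi,
                          NumericMatrix pts_i, IntegerVector start_i,
                          IntegerVector len_i, IntegerVector lab_i,
                          LogicalVector closed_i,
                          NumericVector oj, NumericVector uj, NumericVector vj,
                          NumericMatrix pts_j, IntegerVector start_j,
                          IntegerVector len_j, IntegerVector lab_j,
                          LogicalVector closed_j) {
  // plane normals and intersection line
  V3 Ui = v3(ui[0], ui[1], ui[2]), Vi = v3(vi[0], vi[1], vi[2]);
  V3 Uj = v3(uj[0], uj[1], uj[2]), Vj = v3(vj[0], vj[1], vj[2]);
  V3 Oi = v3(oi[0], oi[1], oi[2]), Oj = v3(oj[0], oj[1], oj[2]);
  V3 ni = cross(Ui, Vi), nj = cross(Uj, Vj);
  if (std::fabs(dot(ni, nj)) > 1.0 - 1e-6) return NA_REAL;  // parallel
  V3 d = cross(ni, nj);
  double dl = norm3(d);
  d = scl(d, 1.0 / dl);
  // point on both planes: solve [ni; nj; d] x = rhs
  double A[9] = { ni[0], ni[1], ni[2], nj[0], nj[1], nj[2], d[0], d[1], d[2] };
  double rhs[3] = { dot(ni, Oi), dot(nj, Oj), dot(d, scl(add(Oi, Oj), 0.5)) };
  // Cramer solve
  double det = A[0] * (A[4] * A[8] - A[5] * A[7]) - A[1] * (A[3] * A[8] - A[5] * A[6]) +
               A[2] * (A[3] * A[7] - A[4] * A[6]);
  if (std::fabs(det) < 1e-12) return NA_REAL;
  auto solve3 = [&](int col) {
    double B[9];
    std::copy(A, A + 9, B);
    B[col] = rhs[0]; B[col + 3] = rhs[1]; B[col + 6] = rhs[2];
    return (B[0] * (B[4] * B[8] - B[5] * B[7]) - B[1] * (B[3] * B[8] - B[5] * B[6]) +
            B[2] * (B[3] * B[7] - B[4] * B[6])) / det;
  };
  V3 p = v3(solve3(0), solve3(1), solve3(2));
  // line in each plane's 2D frame
  V3 ri = sub(p, Oi), rj = sub(p, Oj);
  double p0xi = dot(ri, Ui), p0yi = dot(ri, Vi);
  double dxi = dot(d, Ui), dyi = dot(d, Vi);
  double p0xj = dot(rj, Uj), p0yj = dot(rj, Vj);
  double dxj = dot(d, Uj), dyj = dot(d, Vj);
  std::vector<double> ti[6], tj[6];
  contour_line_crossings(pts_i, start_i, len_i, lab_i, closed_i,
                         p0xi, p0yi, dxi, dyi, ti);
  contour_line_crossings(pts_j, start_j, len_j, lab_j, closed_j,
                         p0xj, p0yj, dxj, dyj, tj);
  // the two in-plane parameterisations measure the same world position along
  // the line up to a constant offset; both use the same p and unit d, so the
  // parameters agree exactly.
  // labels: 1 LV_ENDO, 2 LV_EPI, 3 RV_ENDO, 4 SEPTUM, 5 RV_EPI
  static const int partners[6][4] = {
    {0}, {1, 0, 0, 0}, {2, 4, 0, 0}, {3, 4, 0, 0}, {4, 2, 3, 0}, {0} };
  static const int np[6] = {0, 1, 2, 2, 3, 0};
  double sum = 0.0;
  int count = 0;
  for (int L = 1; L <= 4; ++L) {
    if (ti[L].empty()) continue;
    std::vector<double> partner_t;
    for (int q = 0; q < np[L]; ++q) {
      const std::vector<double>& src = tj[partners[L][q]];
      partner_t.insert(partner_t.end(), src.begin(), src.end());
    }
    std::sort(partner_t.begin(), partner_t.end());
    std::vector<double> a = ti[L];
    std::sort(a.begin(), a.end());
    greedy_match(a, partner_t, sum, count);
  }
  if (count == 0) return NA_REAL;
  return sum / count;
}

// ---------------- safe sliver collapse + surface-aware smoothing ------------

// Collapse the shortest edge of low-quality tets, guarded so the complex
// stays a valid manifold: a collapse is rejected if it would invert an
// incident tet or create a duplicate element. Vertices flagged on_surface are
// re-projected onto the reference surface after merging.
// [[Rcpp::export]]
List cpp_collapse_slivers(NumericMatrix Vin, IntegerMatrix Tin, SEXP bvh_,
                          LogicalVector on_surface_in,
                          double q_thr, double max_len, int rounds) {
  XPtr<TriBVH> bvh(bvh_);
  int nv = Vin.nrow();
  std::vector<V3> V(nv);
  for (int i = 0; i < nv; ++i) V[i] = v3(Vin(i,0), Vin(i,1), Vin(i,2));
  std::vector<std::array<int,4> > T(Tin.nrow());
  for (int k = 0; k < Tin.nrow(); ++k) {
    std::array<int,4> t = {Tin(k,0)-1, Tin(k,1)-1, Tin(k,2)-1, Tin(k,3)-1};
    T[k] = t;
  }
  std::vector<char> on_surface(nv);
  for (int i = 0; i < nv; ++i) on_surface[i] = on_surface_in[i] ? 1 : 0;

  auto tet_vol = [&](const std::array<int,4>& t) {
    V3 e1 = sub(V[t[1]], V[t[0]]);
    V3 e2 = sub(V[t[2]], V[t[0]]);
    V3 e3 = sub(V[t[3]], V[t[0]]);
    return dot(e1, cross(e2, e3)) / 6.0;
  };
  auto tet_key = [&](std::array<int,4> t) {
    std::sort(t.begin(), t.end());
    return (((uint64_t)t[0] * 1000003u ^ (uint64_t)t[1]) * 1000003u ^
            (uint64_t)t[2]) * 1000003u ^ (uint64_t)t[3];
  };

  for (int round = 0; round < rounds; ++round) {
    int m = (int)T.size();
    // vertex -> tets
    std::vector<std::vector<int> > vtet(nv);
    for (int k = 0; k < m; ++k)
      for (int j = 0; j < 4; ++j) vtet[T[k][j]].push_back(k);
    // qualities
    std::vector<double> q(m);
    std::vector<int> bad;
    for (int k = 0; k < m; ++k) {
      q[k] = knupp_one(V[T[k][0]], V[T[k][1]], V[T[k][2]], V[T[k][3]]);
      if (q[k] < q_thr) bad.push_back(k);
    }
    if (bad.empty()) break;
    std::sort(bad.begin(), bad.end(), [&](int a, int b) { return q[a] < q[b]; });
    std::vector<char> touched(nv, 0), dead(m, 0);
    std::vector<int> map(nv);
    for (int i = 0; i < nv; ++i) map[i] = i;
    int done = 0;
    for (int k : bad) {
      if (dead[k]) continue;
      std::array<int,4> t = T[k];
      bool skip = false;
      for (int j = 0; j < 4; ++j) { t[j] = map[t[j]]; if (touched[t[j]]) skip = true; }
      if (skip) continue;
      // shortest edge
      static const int E[6][2] = { {0,1},{0,2},{0,3},{1,2},{1,3},{2,3} };
      int besta = -1, bestb = -1;
      double bestl = max_len;
      for (int e = 0; e < 6; ++e) {
        int a = t[E[e][0]], b = t[E[e][1]];
        if (a == b) continue;
        double l = norm3(sub(V[a], V[b]));
        if (l < bestl) { bestl = l; besta = a; bestb = b; }
      }
      if (besta < 0) continue;
      int a = besta, b = bestb;
      // trial position
      V3 old_a = V[a];
      V3 mid = scl(add(V[a], V[b]), 0.5);
      V3 trial;
      if (on_surface[a] && on_surface[b]) {
        V3 qn; int tri;
        bvh->nearest(mid, qn, tri);
        trial = qn;
      } else if (on_surface[a]) trial = V[a];
      else if (on_surface[b]) trial = V[b];
      else trial = mid;
      V[a] = trial;
      // validate all tets incident to a or b (post-merge)
      bool ok = true;
      std::unordered_map<uint64_t, int> seen;
      std::vector<int> affected;
      for (int pass = 0; pass < 2 && ok; ++pass) {
        int v = pass == 0 ? a : b;
        for (int kk : vtet[v]) {
          if (dead[kk]) continue;
          std::array<int,4> tt = T[kk];
          bool has_a = false, has_b = false;
          for (int j = 0; j < 4; ++j) {
            tt[j] = map[tt[j]];
            if (tt[j] == b) { tt[j] = a; has_b = true; }
            if (tt[j] == a) has_a = true;
          }
          bool degen = false;
          for (int x = 0; x < 4 && !degen; ++x)
            for (int y = x + 1; y < 4; ++y)
              if (tt[x] == tt[y]) { degen = true; break; }
          if (degen) continue;  // dies with the collapse
          if (tet_vol(tt) < 1e-10) { ok = false; break; }
          uint64_t key = tet_key(tt);
          auto it = seen.find(key);
          if (it != seen.end() && it->second != kk) { ok = false; break; }
          seen[key] = kk;
          affected.push_back(kk);
          (void)has_a; (void)has_b;
        }
      }
      if (!ok) { V[a] = old_a; continue; }
      // commit
      map[b] = a;
      on_surface[a] = on_surface[a] || on_surface[b];
      touched[a] = touched[b] = 1;
      for (int kk : vtet[b]) {
        if (dead[kk]) continue;
        std::array<int,4> tt = T[kk];
        bool degen = false;
        int rep[4];
        for (int j = 0; j < 4; ++j) { rep[j] = map[tt[j]] == b ? a : map[tt[j]]; }
        for (int x = 0; x < 4 && !degen; ++x)
          for (int y = x + 1; y < 4; ++y) if (rep[x] == rep[y]) degen = true;
        if (degen) dead[kk] = 1;
      }
      ++done;
    }
    if (done == 0) break;
    // apply the vertex mapping and drop dead/degenerate tets
    std::vector<std::array<int,4> > T2;
    T2.reserve(T.size());
    for (int k = 0; k < m; ++k) {
      if (dead[k]) continue;
      std::array<int,4> tt = T[k];
      bool degen = false;
      for (int j = 0; j < 4; ++j) {
        int v = tt[j];
        while (map[v] != v) v = map[v];
        tt[j] = v;
      }
      for (int x = 0; x < 4 && !degen; ++x)
        for (int y = x + 1; y < 4; ++y) if (tt[x] == tt[y]) degen = true;
      if (!degen) T2.push_back(tt);
    }
    T.swap(T2);
  }
  // compact
  std::vector<int> remap(nv, -1);
  int nu = 0;
  for (auto& t : T) for (int j = 0; j < 4; ++j) if (remap[t[j]] < 0) remap[t[j]] = nu++;
  NumericMatrix VO(nu, 3);
  LogicalVector OS(nu);
  for (int i = 0; i < nv; ++i)
    if (remap[i] >= 0) {
      for (int d = 0; d < 3; ++d) VO(remap[i], d) = V[i][d];
      OS[remap[i]] = on_surface[i] != 0;
    }
  IntegerMatrix TO(T.size(), 4);
  for (size_t k = 0; k < T.size(); ++k)
    for (int j = 0; j < 4; ++j) TO(k, j) = remap[T[k][j]] + 1;
  return List::create(_["vertices"] = VO, _["tets"] = TO, _["on_surface"] = OS);
}

// Quality-guarded smoothing; vertices flagged on_surface move along the
// surface (smoothed position re-projected via the BVH), others move freely.
// A move is kept only if the minimum incident quality does not decrease and
// no incident element inverts.
// [[Rcpp::export]]
NumericMatrix cpp_improve_tets_surface(NumericMatrix Vin, IntegerMatrix Tin,
                                       LogicalVector on_surface, SEXP bvh_,
                                       int iters, double q_skip) {
  XPtr<TriBVH> bvh(bvh_);
  int nv = Vin.nrow(), m = Tin.nrow();
  std::vector<V3> V(nv);
  for (int i = 0; i < nv; ++i) V[i] = v3(Vin(i,0), Vin(i,1), Vin(i,2));
  std::vector<std::array<int,4> > T(m);
  std::vector<std::vector<int> > vtet(nv);
  for (int k = 0; k < m; ++k) {
    std::array<int,4> t = {Tin(k,0)-1, Tin(k,1)-1, Tin(k,2)-1, Tin(k,3)-1};
    T[k] = t;
    for (int j = 0; j < 4; ++j) vtet[t[j]].push_back(k);
  }
  std::vector<std::vector<int> > nbr(nv);
  for (int k = 0; k < m; ++k)
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        if (a != b) nbr[T[k][a]].push_back(T[k][b]);
  for (int i = 0; i < nv; ++i) {
    std::sort(nbr[i].begin(), nbr[i].end());
    nbr[i].erase(std::unique(nbr[i].begin(), nbr[i].end()), nbr[i].end());
  }
  auto local_min_q = [&](int vi) {
    double q = 1.0;
    for (int k : vtet[vi]) {
      double s = knupp_one(V[T[k][0]], V[T[k][1]], V[T[k][2]], V[T[k][3]]);
      if (s < q) q = s;
    }
    return q;
  };
  auto local_min_vol = [&](int vi) {
    double q = std::numeric_limits<double>::infinity();
    for (int k : vtet[vi]) {
      V3 e1 = sub(V[T[k][1]], V[T[k][0]]);
      V3 e2 = sub(V[T[k][2]], V[T[k][0]]);
      V3 e3 = sub(V[T[k][3]], V[T[k][0]]);
      double vol = dot(e1, cross(e2, e3));
      if (vol < q) q = vol;
    }
    return q;
  };
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < nv; ++i) {
      if (nbr[i].empty() || vtet[i].empty()) continue;
      double q0 = local_min_q(i);
      if (q0 > q_skip) continue;
      V3 mean = v3(0, 0, 0);
      for (int j : nbr[i]) mean = add(mean, V[j]);
      mean = scl(mean, 1.0 / nbr[i].size());
      V3 old = V[i];
      double bestq = q0;
      V3 bestp = old;
      for (double w : {1.0, 0.5, 0.25}) {
        V3 cand = add(scl(old, 1.0 - w), scl(mean, w));
        if (on_surface[i]) {
          V3 qn; int tri;
          bvh->nearest(cand, qn, tri);
          cand = qn;
        }
        V[i] = cand;
        if (local_min_vol(i) > 1e-12) {
          double q = local_min_q(i);
          if (q > bestq + 1e-12) { bestq = q; bestp = cand; }
        }
      }
      V[i] = bestp;
    }
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = V[i][d];
  return out;
}

// ---------------- intensity-profile dissimilarity (hot path) ---------------

// 1 - NCC of two phase images sampled bilinearly along the planes'
// intersection line; mirrors the R reference (sample_profiles + ncc).
// [[Rcpp::export]]
double cpp_profile_pair_E(NumericVector oi, NumericVector ui, NumericVector vi,
                          NumericVector spi, IntegerVector shi, NumericMatrix img_i,
                          NumericVector oj, NumericVector uj, NumericVector vj,
                          NumericVector spj, IntegerVector shj, NumericMatrix img_j,
                          double step, int min_samples) {
  V3 Ui = v3(ui[0], ui[1], ui[2]), Vi = v3(vi[0], vi[1], vi[2]);
  V3 Uj = v3(uj[0], uj[1], uj[2]), Vj = v3(vj[0], vj[1], vj[2]);
  V3 Oi = v3(oi[0], oi[1], oi[2]), Oj = v3(oj[0], oj[1], oj[2]);
  V3 ni = cross(Ui, Vi), nj = cross(Uj, Vj);
  if (std::fabs(dot(ni, nj)) > 1.0 - 1e-6) return NA_REAL;
  V3 d = cross(ni, nj);
  d = scl(d, 1.0 / norm3(d));
  double A[9] = { ni[0], ni[1], ni[2], nj[0], nj[1], nj[2], d[0], d[1], d[2] };
  double rhs[3] = { dot(ni, Oi), dot(nj, Oj), dot(d, scl(add(Oi, Oj), 0.5)) };
  double det = A[0] * (A[4] * A[8] - A[5] * A[7]) - A[1] * (A[3] * A[8] - A[5] * A[6]) +
               A[2] * (A[3] * A[7] - A[4] * A[6]);
  if (std::fabs(det) < 1e-12) return NA_REAL;
  auto solve3 = [&](int col) {
    double B[9];
    std::copy(A, A + 9, B);
    B[col] = rhs[0]; B[col + 3] = rhs[1]; B[col + 6] = rhs[2];
    return (B[0] * (B[4] * B[8] - B[5] * B[7]) - B[1] * (B[3] * B[8] - B[5] * B[6]) +
            B[2] * (B[3] * B[7] - B[4] * B[6])) / det;
  };
  V3 p = v3(solve3(0), solve3(1), solve3(2));
  // clip the line parameter to both pixel rectangles
  auto clip_range = [&](const V3& O, const V3& U, const V3& Vv,
                        const NumericVector& sp, const IntegerVector& sh,
                        double& t0, double& t1) -> bool {
    V3 r = sub(p, O);
    double px = dot(r, U), py = dot(r, Vv);
    double dx = dot(d, U), dy = dot(d, Vv);
    double ex = (sh[1] - 1) * sp[0], ey = (sh[0] - 1) * sp[1];
    t0 = -std::numeric_limits<double>::infinity();
    t1 = std::numeric_limits<double>::infinity();
    double pp[2] = {px, py}, dd[2] = {dx, dy}, ee[2] = {ex, ey};
    for (int k = 0; k < 2; ++k) {
      if (std::fabs(dd[k]) < 1e-12) {
        if (pp[k] < 0 || pp[k] > ee[k]) return false;
      } else {
        double ta = (0 - pp[k]) / dd[k], tb = (ee[k] - pp[k]) / dd[k];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta); t1 = std::min(t1, tb);
      }
    }
    return std::isfinite(t0) && std::isfinite(t1) && t1 > t0;
  };
  double a0, a1, b0, b1;
  if (!clip_range(Oi, Ui, Vi, spi, shi, a0, a1)) return NA_REAL;
  if (!clip_range(Oj, Uj, Vj, spj, shj, b0, b1)) return NA_REAL;
  double t0 = std::max(a0, b0), t1 = std::min(a1, b1);
  if (t1 - t0 < (min_samples - 1) * step) return NA_REAL;
  int n = (int)std::floor((t1 - t0) / step) + 1;
  auto sample = [&](const V3& O, const V3& U, const V3& Vv,
                    const NumericVector& sp, const IntegerVector& sh,
                    const NumericMatrix& img, double t) -> double {
    V3 w = add(p, scl(d, t));
    V3 r = sub(w, O);
    double xj = dot(r, U) / sp[0];
    double yi = dot(r, Vv) / sp[1];
    int nr = sh[0], nc = sh[1];
    if (xj < 0 || yi < 0 || xj > nc - 1 || yi > nr - 1) return NA_REAL;
    int j0 = std::min((int)std::floor(xj), nc - 2);
    int i0 = std::min((int)std::floor(yi), nr - 2);
    if (j0 < 0) j0 = 0;
    if (i0 < 0) i0 = 0;
    double fx = xj - j0, fy = yi - i0;
    double v00 = img(i0, j0), v01 = img(i0, j0 + 1);
    double v10 = img(i0 + 1, j0), v11 = img(i0 + 1, j0 + 1);
    if (ISNAN(v00) || ISNAN(v01) || ISNAN(v10) || ISNAN(v11)) {
      // NA handling identical to the bilinear sampler: any NA corner with
      // nonzero weight poisons the sample
      double va = ISNAN(v00) || ISNAN(v01) ? NA_REAL : v00 * (1 - fx) + v01 * fx;
      double vb = ISNAN(v10) || ISNAN(v11) ? NA_REAL : v10 * (1 - fx) + v11 * fx;
      if (ISNAN(va) || ISNAN(vb)) return NA_REAL;
      return va * (1 - fy) + vb * fy;
    }
    return (v00 * (1 - fx) + v01 * fx) * (1 - fy) + (v10 * (1 - fx) + v11 * fx) * fy;
  };
  std::vector<double> sa, sb;
  sa.reserve(n); sb.reserve(n);
  for (int k = 0; k < n; ++k) {
    double t = t0 + k * step;
    double va = sample(Oi, Ui, Vi, spi, shi, img_i, t);
    double vb = sample(Oj, Uj, Vj, spj, shj, img_j, t);
    if (ISNAN(va) || ISNAN(vb)) continue;
    sa.push_back(va); sb.push_back(vb);
  }
  int m = (int)sa.size();
  if (m < min_samples) return NA_REAL;
  double ma = 0, mb = 0;
  for (int k = 0; k < m; ++k) { ma += sa[k]; mb += sb[k]; }
  ma /= m; mb /= m;
  double sab = 0, saa = 0, sbb = 0;
  for (int k = 0; k < m; ++k) {
    sab += (sa[k] - ma) * (sb[k] - mb);
    saa += (sa[k] - ma) * (sa[k] - ma);
    sbb += (sb[k] - mb) * (sb[k] - mb);
  }
  if (saa <= 0 || sbb <= 0) return NA_REAL;
  return 1.0 - sab / std::sqrt(saa * sbb);
}
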