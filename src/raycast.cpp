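#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <queue>

using namespace Rcpp;

// Axis-aligned bounding volume hierarchy over triangles, median split on the
// longest centroid axis. Rays are cast with unnormalised direction
// ((u-cx)/fx, (v-cy)/fy, 1) so the intersection parameter t equals the camera
// Z depth directly.

struct BVHNode {
  double bmin[3], bmax[3];
  int left, right;   // child node indices, -1 for leaf
  int start, count;  // triangle range for leaves
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;           // triangle indices in leaf ranges
  const double *vx, *vy, *vz;       // vertex coordinates (n)
  const int *f0, *f1, *f2;          // 0-based face indices (m)
  int ntri;
};

static void node_bounds(BVH &b, int start, int count,
                        const std::vector<double> &cx,
                        const std::vector<double> &cy,
                        const std::vector<double> &cz,
                        BVHNode &nd) {
  for (int a = 0; a < 3; ++a) { nd.bmin[a] = 1e300; nd.bmax[a] = -1e300; }
  for (int i = start; i < start + count; ++i) {
    int t = b.order[i];
    int id[3] = { b.f0[t], b.f1[t], b.f2[t] };
    for (int k = 0; k < 3; ++k) {
      double p[3] = { b.vx[id[k]], b.vy[id[k]], b.vz[id[k]] };
      for (int a = 0; a < 3; ++a) {
        if (p[a] < nd.bmin[a]) nd.bmin[a] = p[a];
        if (p[a] > nd.bmax[a]) nd.bmax[a] = p[a];
      }
    }
  }
  (void)cx; (void)cy; (void)cz;
}

static int build_node(BVH &b, int start, int count,
                      const std::vector<double> &cx,
                      const std::vector<double> &cy,
                      const std::vector<double> &cz) {
  BVHNode nd;
  node_bounds(b, start, count, cx, cy, cz, nd);
  nd.left = nd.right = -1; nd.start = start; nd.count = count;
  int self = (int)b.nodes.size();
  b.nodes.push_back(nd);
  if (count <= 4) return self;
  // split on longest axis of centroid extent
  double cmin[3] = {1e300,1e300,1e300}, cmax[3] = {-1e300,-1e300,-1e300};
  for (int i = start; i < start + count; ++i) {
    int t = b.order[i];
    double c[3] = { cx[t], cy[t], cz[t] };
    for (int a = 0; a < 3; ++a) {
      if (c[a] < cmin[a]) cmin[a] = c[a];
      if (c[a] > cmax[a]) cmax[a] = c[a];
    }
  }
  int axis = 0; double best = cmax[0] - cmin[0];
  for (int a = 1; a < 3; ++a)
    if (cmax[a] - cmin[a] > best) { best = cmax[a] - cmin[a]; axis = a; }
  if (best <= 0) return self;
  int mid = start + count / 2;
  const std::vector<double> &cc = (axis == 0 ? cx : (axis == 1 ? cy : cz));
  std::nth_element(b.order.begin() + start, b.order.begin() + mid,
                   b.order.begin() + start + count,
                   [&cc](int i, int j) { return cc[i] < cc[j]; });
  int l = build_node(b, start, mid - start, cx, cy, cz);
  int r = build_node(b, mid, start + count - mid, cx, cy, cz);
  b.nodes[self].left = l;
  b.nodes[self].right = r;
  return self;
}

static inline bool box_hit(const BVHNode &nd, const double o[3],
                           const double inv[3], double tmax) {
  double t0 = 0.0, t1 = tmax;
  for (int a = 0; a < 3; ++a) {
    double ta = (nd.bmin[a] - o[a]) * inv[a];
    double tb = (nd.bmax[a] - o[a]) * inv[a];
    if (ta > tb) std::swap(ta, tb);
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
    if (t0 > t1) return false;
  }
  return true;
}

// Moller-Trumbore; returns t or -1
static inline double tri_hit(const BVH &b, int t, const double o[3],
                             const double d[3]) {
  const double EPS = 1e-12;
  int i0 = b.f0[t], i1 = b.f1[t], i2 = b.f2[t];
  double e1[3] = { b.vx[i1]-b.vx[i0], b.vy[i1]-b.vy[i0], b.vz[i1]-b.vz[i0] };
  double e2[3] = { b.vx[i2]-b.vx[i0], b.vy[i2]-b.vy[i0], b.vz[i2]-b.vz[i0] };
  double p[3] = { d[1]*e2[2]-d[2]*e2[1], d[2]*e2[0]-d[0]*e2[2],
                  d[0]*e2[1]-d[1]*e2[0] };
  double det = e1[0]*p[0] + e1[1]*p[1] + e1[2]*p[2];
  if (std::fabs(det) < EPS) return -1.0;
  double idet = 1.0 / det;
  double s[3] = { o[0]-b.vx[i0], o[1]-b.vy[i0], o[2]-b.vz[i0] };
  double u = (s[0]*p[0] + s[1]*p[1] + s[2]*p[2]) * idet;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  double q[3] = { s[1]*e1[2]-s[2]*e1[1], s[2]*e1[0]-s[0]*e1[2],
                  s[0]*e1[1]-s[1]*e1[0] };
  double v = (d[0]*q[0] + d[1]*q[1] + d[2]*q[2]) * idet;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double tt = (e2[0]*q[0] + e2[1]*q[1] + e2[2]*q[2]) * idet;
  return tt;
}

static double raycast(const BVH &b, const double o[3], const double d[3]) {
  double inv[3];
  for (int a = 0; a < 3; ++a)
    inv[a] = (d[a] != 0.0) ? 1.0 / d[a] : 1e300;
  double best = 1e300;
  int stack[64]; int sp = 0;
  stack[sp++] = 0;
  while (sp > 0) {
    const BVHNode &nd = b.nodes[stack[--sp]];
    if (!box_hit(nd, o, inv, best)) continue;
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        double t = tri_hit(b, b.order[i], o, d);
        if (t > 1e-9 && t < best) best = t;
      }
    } else {
      if (sp < 62) { stack[sp++] = nd.left; stack[sp++] = nd.right; }
    }
  }
  return (best < 1e300) ? best : 0.0;
}

// [[Rcpp::export(name = ".render_depth_cpp")]]
NumericMatrix render_depth_cpp(NumericMatrix verts, IntegerMatrix faces,
                               double fx, double fy, double cx, double cy,
                               int width, int height) {
  int ntri = faces.nrow();
  NumericMatrix out(height, width);
  if (ntri == 0 || verts.nrow() == 0) return out;

  std::vector<double> vx(verts.nrow()), vy(verts.nrow()), vz(verts.nrow());
  for (int i = 0; i < verts.nrow(); ++i) {
    vx[i] = verts(i, 0); vy[i] = verts(i, 1); vz[i] = verts(i, 2);
  }
  std::vector<int> f0(ntri), f1(ntri), f2(ntri);
  std::vector<double> ccx(ntri), ccy(ntri), ccz(ntri);
  for (int t = 0; t < ntri; ++t) {
    f0[t] = faces(t, 0) - 1; f1[t] = faces(t, 1) - 1; f2[t] = faces(t, 2) - 1;
    ccx[t] = (vx[f0[t]] + vx[f1[t]] + vx[f2[t]]) / 3.0;
    ccy[t] = (vy[f0[t]] + vy[f1[t]] + vy[f2[t]]) / 3.0;
    ccz[t] = (vz[f0[t]] + vz[f1[t]] + vz[f2[t]]) / 3.0;
  }
  BVH b;
  b.vx = vx.data(); b.vy = vy.data(); b.vz = vz.data();
  b.f0 = f0.data(); b.f1 = f1.data(); b.f2 = f2.data();
  b.ntri = ntri;
  b.order.resize(ntri);
  for (int t = 0; t < ntri; ++t) b.order[t] = t;
  b.nodes.reserve(2 * ntri / 4 + 8);
  build_node(b, 0, ntri, ccx, ccy, ccz);

  double o[3] = {0.0, 0.0, 0.0};
  for (int u = 0; u < width; ++u) {
    double dx = (u - cx) / fx;
    for (int v = 0; v < height; ++v) {
      double d[3] = { dx, (v - cy) / fy, 1.0 };
      out(v, u) = raycast(b, o, d);
    }
  }
  return out;
}

// 4-connected component labelling of a logical matrix; returns integer labels
// (0 = background), labelled in discovery order.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<int> qs; qs.reserve(1024);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      qs.clear();
      qs.push_back(i + j * h);
      lab(i, j) = next;
      while (!qs.empty()) {
        int p = qs.back(); qs.pop_back();
        int pi = p % h, pj = p / h;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ni = pi + di[k], nj = pj + dj[k];
          if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            qs.push_back(ni + nj * h);
          }
        }
      }
    }
  }
  return lab;
}
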