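// Geometry kernels: iso-surface area/volume via marching tetrahedra,
// maximum pairwise distance, 26-connected component labeling.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Vec3 { double x, y, z; };

static inline Vec3 lerp_edge(const Vec3& a, const Vec3& b, double fa, double fb,
                             double iso) {
  double t = (iso - fa) / (fb - fa);
  Vec3 v;
  v.x = a.x + t * (b.x - a.x);
  v.y = a.y + t * (b.y - a.y);
  v.z = a.z + t * (b.z - a.z);
  return v;
}

static inline Vec3 vsub(const Vec3& a, const Vec3& b) {
  Vec3 v; v.x = a.x - b.x; v.y = a.y - b.y; v.z = a.z - b.z; return v;
}
static inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  Vec3 v;
  v.x = a.y * b.z - a.z * b.y;
  v.y = a.z * b.x - a.x * b.z;
  v.z = a.x * b.y - a.y * b.x;
  return v;
}
static inline double vdot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// Accumulate one oriented triangle: orientation fixed so the normal points
// away from `inside` (a vertex on the >= iso side). Contributes to surface
// area and, via the divergence theorem, to the enclosed volume.
static void add_tri(Vec3 p0, Vec3 p1, Vec3 p2, const Vec3& inside,
                    double& area, double& volume) {
  Vec3 n = vcross(vsub(p1, p0), vsub(p2, p0));
  Vec3 c;
  c.x = (p0.x + p1.x + p2.x) / 3.0 - inside.x;
  c.y = (p0.y + p1.y + p2.y) / 3.0 - inside.y;
  c.z = (p0.z + p1.z + p2.z) / 3.0 - inside.z;
  if (vdot(n, c) < 0) { Vec3 tmp = p1; p1 = p2; p2 = tmp; n = vcross(vsub(p1, p0), vsub(p2, p0)); }
  area += 0.5 * std::sqrt(vdot(n, n));
  // signed tet volume with apex at origin; outward orientation sums to the
  // enclosed volume for a closed surface
  volume += vdot(p0, vcross(p1, p2)) / 6.0;
}

static void do_tet(const Vec3 p[4], const double f[4], double iso,
                   double& area, double& volume) {
  int in[4], nin = 0, nout = 0, outv[4];
  for (int i = 0; i < 4; ++i) {
    if (f[i] >= iso) in[nin++] = i; else outv[nout++] = i;
  }
  if (nin == 0 || nin == 4) return;
  if (nin == 1) {
    int a = in[0];
    Vec3 q0 = lerp_edge(p[a], p[outv[0]], f[a], f[outv[0]], iso);
    Vec3 q1 = lerp_edge(p[a], p[outv[1]], f[a], f[outv[1]], iso);
    Vec3 q2 = lerp_edge(p[a], p[outv[2]], f[a], f[outv[2]], iso);
    add_tri(q0, q1, q2, p[a], area, volume);
  } else if (nin == 3) {
    int a = outv[0];
    Vec3 q0 = lerp_edge(p[in[0]], p[a], f[in[0]], f[a], iso);
    Vec3 q1 = lerp_edge(p[in[1]], p[a], f[in[1]], f[a], iso);
    Vec3 q2 = lerp_edge(p[in[2]], p[a], f[in[2]], f[a], iso);
    add_tri(q0, q1, q2, p[in[0]], area, volume);
  } else {
    // two in (i0,i1), two out (o0,o1): quad i0o0 - i1o0 - i1o1 - i0o1
    int i0 = in[0], i1 = in[1], o0 = outv[0], o1 = outv[1];
    Vec3 a00 = lerp_edge(p[i0], p[o0], f[i0], f[o0], iso);
    Vec3 a10 = lerp_edge(p[i1], p[o0], f[i1], f[o0], iso);
    Vec3 a11 = lerp_edge(p[i1], p[o1], f[i1], f[o1], iso);
    Vec3 a01 = lerp_edge(p[i0], p[o1], f[i0], f[o1], iso);
    add_tri(a00, a10, a11, p[i0], area, volume);
    add_tri(a00, a11, a01, p[i0], area, volume);
  }
}

// 6-tetrahedra decomposition of each cell, all sharing the main diagonal
// v0-v6 so that faces match between neighboring cells.
static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
// cube corner offsets (dx, dy, dz)
static const int CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

// [[Rcpp::export(name = ".mesh_area_volume")]]
NumericVector mesh_area_volume(NumericVector field, IntegerVector dim,
                               NumericVector spacing, double iso) {
  const int D = dim[0], H = dim[1], W = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double* fp = field.begin();
  double area = 0.0, volume = 0.0;
  for (int k = 0; k + 1 < W; ++k) {
    for (int j = 0; j + 1 < H; ++j) {
      for (int i = 0; i + 1 < D; ++i) {
        double fc[8];
        Vec3 pc[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          const int ii = i + CORNER[c][0], jj = j + CORNER[c][1],
                    kk = k + CORNER[c][2];
          fc[c] = fp[ii + (size_t)D * (jj + (size_t)H * kk)];
          pc[c].x = ii * sx; pc[c].y = jj * sy; pc[c].z = kk * sz;
          if (fc[c] >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          Vec3 tp[4]; double tf[4];
          for (int v = 0; v < 4; ++v) {
            tp[v] = pc[TETS[t][v]];
            tf[v] = fc[TETS[t][v]];
          }
          do_tet(tp, tf, iso, area, volume);
        }
      }
    }
  }
  return NumericVector::create(area, volume);
}

// [[Rcpp::export(name = ".max_pairwise_dist")]]
double max_pairwise_dist(NumericMatrix coords) {
  const int n = coords.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - coords(j, 0), dy = yi - coords(j, 1),
                   dz = zi - coords(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Label 26-connected components of equal-valued voxels; voxels with value
// NA_INTEGER (outside mask) get label 0. Returns integer array of labels.
// [[Rcpp::export(name = ".label_components26")]]
IntegerVector label_components26(IntegerVector vol, IntegerVector dim) {
  const int D = dim[0], H = dim[1], W = dim[2];
  const size_t n = (size_t)D * H * W;
  IntegerVector labels(n);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (vol[s] == NA_INTEGER || labels[s] != 0) continue;
    const int level = vol[s];
    ++next;
    labels[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      const int i = cur % D, j = (cur / D) % H, k = cur / ((size_t)D * H);
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= W) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= H) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int ii = i + di;
            if (ii < 0 || ii >= D) continue;
            const size_t idx = ii + (size_t)D * (jj + (size_t)H * kk);
            if (labels[idx] == 0 && vol[idx] != NA_INTEGER && vol[idx] == level) {
              labels[idx] = next;
              stack.push_back(idx);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}
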