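// Texture matrix kernels: GLCM pair counts and GLRLM run counts over the
// 13 unique 3D directions at distance 1. Voxels outside the mask are
// NA_INTEGER and break pairs/runs; gray levels are 1..Ng.
#include <Rcpp.h>
using namespace Rcpp;

static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// [[Rcpp::export(name = ".glcm_counts")]]
NumericVector glcm_counts(IntegerVector vol, IntegerVector dim, int ng) {
  const int D = dim[0], H = dim[1], W = dim[2];
  NumericVector out((size_t)ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    const int di = DIRS[d][0], dj = DIRS[d][1], dk = DIRS[d][2];
    double* slab = out.begin() + (size_t)d * ng * ng;
    for (int k = 0; k < W; ++k) {
      const int kk = k + dk;
      if (kk < 0 || kk >= W) continue;
      for (int j = 0; j < H; ++j) {
        const int jj = j + dj;
        if (jj < 0 || jj >= H) continue;
        for (int i = 0; i < D; ++i) {
          const int ii = i + di;
          if (ii < 0 || ii >= D) continue;
          const int a = vol[i + (size_t)D * (j + (size_t)H * k)];
          if (a == NA_INTEGER) continue;
          const int b = vol[ii + (size_t)D * (jj + (size_t)H * kk)];
          if (b == NA_INTEGER) continue;
          // symmetric matrix: count the pair in both orders
          slab[(a - 1) + (size_t)ng * (b - 1)] += 1.0;
          slab[(b - 1) + (size_t)ng * (a - 1)] += 1.0;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// [[Rcpp::export(name = ".glrlm_counts")]]
NumericVector glrlm_counts(IntegerVector vol, IntegerVector dim, int ng) {
  const int D = dim[0], H = dim[1], W = dim[2];
  int lmax = D;
  if (H > lmax) lmax = H;
  if (W > lmax) lmax = W;
  NumericVector out((size_t)ng * lmax * 13);
  for (int d = 0; d < 13; ++d) {
    const int di = DIRS[d][0], dj = DIRS[d][1], dk = DIRS[d][2];
    double* slab = out.begin() + (size_t)d * ng * lmax;
    for (int k = 0; k < W; ++k) {
      for (int j = 0; j < H; ++j) {
        for (int i = 0; i < D; ++i) {
          const int v = vol[i + (size_t)D * (j + (size_t)H * k)];
          if (v == NA_INTEGER) continue;
          // run start: predecessor along -d is out of grid, out of mask,
          // or a different level
          const int pi = i - di, pj = j - dj, pk = k - dk;
          if (pi >= 0 && pi < D && pj >= 0 && pj < H && pk >= 0 && pk < W) {
            const int pv = vol[pi + (size_t)D * (pj + (size_t)H * pk)];
            if (pv != NA_INTEGER && pv == v) continue;
          }
          int len = 1;
          int ci = i + di, cj = j + dj, ck = k + dk;
          while (ci >= 0 && ci < D && cj >= 0 && cj < H && ck >= 0 && ck < W) {
            const int cv = vol[ci + (size_t)D * (cj + (size_t)H * ck)];
            if (cv == NA_INTEGER || cv != v) break;
            ++len;
            ci += di; cj += dj; ck += dk;
          }
          slab[(v - 1) + (size_t)ng * (len - 1)] += 1.0;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ng, lmax, 13);
  return out;
}
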