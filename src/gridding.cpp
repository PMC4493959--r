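#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Kaiser-Bessel kernel value at offset u (grid cells) for full width `width`.
static inline double kbval(double u, double halfw, double beta) {
  double t = u / halfw;
  double arg = 1.0 - t * t;
  if (arg <= 0.0) return 0.0;
  return R::bessel_i(beta * std::sqrt(arg), 0.0, 1.0);
}

static inline int wrap(int i, int n) {
  i %= n;
  return i < 0 ? i + n : i;
}

// Per-sample separable kernel weights along one axis.
// Fills idx (wrapped grid indices) and w (kernel values); returns support size.
static inline int axis_weights(double g, int G, int width, double halfw,
                               double beta, int *idx, double *w) {
  int lo = (int)std::ceil(g - halfw);
  int hi = (int)std::floor(g + halfw);
  int m = 0;
  for (int j = lo; j <= hi; ++j) {
    double kv = kbval(g - j, halfw, beta);
    if (kv > 0.0) {
      idx[m] = wrap(j, G);
      w[m] = kv;
      ++m;
    }
  }
  return m;
}

// Spread non-Cartesian samples onto an oversampled G^3 grid (adjoint of
// interpolation). `kg` holds sample positions in grid units (0..G), periodic.
// [[Rcpp::export]]
ComplexVector cpp_kb_spread(ComplexVector samples, NumericMatrix kg,
                            int G, int width, double beta) {
  int n = samples.size();
  if (kg.nrow() != n) stop("sample/trajectory length mismatch");
  ComplexVector out(G * G * G);
  double halfw = width / 2.0;
  std::vector<int> ix(width + 2), iy(width + 2), iz(width + 2);
  std::vector<double> wx(width + 2), wy(width + 2), wz(width + 2);
  for (int s = 0; s < n; ++s) {
    double re = samples[s].r, im = samples[s].i;
    int mx = axis_weights(kg(s, 0), G, width, halfw, beta, ix.data(), wx.data());
    int my = axis_weights(kg(s, 1), G, width, halfw, beta, iy.data(), wy.data());
    int mz = axis_weights(kg(s, 2), G, width, halfw, beta, iz.data(), wz.data());
    for (int c = 0; c < mz; ++c) {
      double wzc = wz[c];
      R_xlen_t oz = (R_xlen_t)iz[c] * G * G;
      for (int b = 0; b < my; ++b) {
        double wyz = wy[b] * wzc;
        R_xlen_t oy = oz + (R_xlen_t)iy[b] * G;
        for (int a = 0; a < mx; ++a) {
          double w = wx[a] * wyz;
          R_xlen_t o = oy + ix[a];
          out[o].r += re * w;
          out[o].i += im * w;
        }
      }
    }
  }
  return out;
}

// Interpolate an oversampled G^3 grid at non-Cartesian sample positions
// (forward counterpart of cpp_kb_spread; exact adjoint pair).
// [[Rcpp::export]]
ComplexVector cpp_kb_interp(ComplexVector grid, NumericMatrix kg,
                            int G, int width, double beta) {
  if (grid.size() != (R_xlen_t)G * G * G) stop("grid size does not match G^3");
  int n = kg.nrow();
  ComplexVector out(n);
  double halfw = width / 2.0;
  std::vector<int> ix(width + 2), iy(width + 2), iz(width + 2);
  std::vector<double> wx(width + 2), wy(width + 2), wz(width + 2);
  for (int s = 0; s < n; ++s) {
    int mx = axis_weights(kg(s, 0), G, width, halfw, beta, ix.data(), wx.data());
    int my = axis_weights(kg(s, 1), G, width, halfw, beta, iy.data(), wy.data());
    int mz = axis_weights(kg(s, 2), G, width, halfw, beta, iz.data(), wz.data());
    double re = 0.0, im = 0.0;
    for (int c = 0; c < mz; ++c) {
      double wzc = wz[c];
      R_xlen_t oz = (R_xlen_t)iz[c] * G * G;
      for (int b = 0; b < my; ++b) {
        double wyz = wy[b] * wzc;
        R_xlen_t oy = oz + (R_xlen_t)iy[b] * G;
        for (int a = 0; a < mx; ++a) {
          double w = wx[a] * wyz;
          R_xlen_t o = oy + ix[a];
          re += grid[o].r * w;
          im += grid[o].i * w;
        }
      }
    }
    out[s].r = re;
    out[s].i = im;
  }
  return out;
}

// 6-connected component of `mask` containing `seed` (1-based linear index).
// [[Rcpp::export]]
LogicalVector cpp_flood_fill6(LogicalVector mask, IntegerVector dims,
                              int seed) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask size does not match dims");
  LogicalVector out(n);
  R_xlen_t s = seed - 1;
  if (s < 0 || s >= n || !mask[s]) return out;
  std::vector<char> seen(n, 0);
  std::queue<R_xlen_t> q;
  q.push(s);
  seen[s] = 1;
  while (!q.empty()) {
    R_xlen_t v = q.front();
    q.pop();
    out[v] = TRUE;
    int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int d = 0; d < 6; ++d) {
      int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (mask[u] && !seen[u]) {
        seen[u] = 1;
        q.push(u);
      }
    }
  }
  return out;
}
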