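#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
#include <limits>

using namespace Rcpp;

// clamp index to [0, n-1] (replicate border)
static inline int clampi(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }

// Median filter with a (2r+1)^d cubic neighbourhood, replicate borders.
// x is a 2D or 3D array in R's column-major layout with dims d.
// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector x, IntegerVector dim, int radius) {
  int nd = dim.size();
  int n0 = dim[0], n1 = nd > 1 ? dim[1] : 1, n2 = nd > 2 ? dim[2] : 1;
  NumericVector out(x.size());
  int w = 2 * radius + 1;
  int nn = nd == 3 ? w * w * w : w * w;
  std::vector<double> buf(nn);
  for (int k = 0; k < n2; ++k) {
    for (int j = 0; j < n1; ++j) {
      for (int i = 0; i < n0; ++i) {
        int m = 0;
        int kk0 = nd == 3 ? -radius : 0, kk1 = nd == 3 ? radius : 0;
        for (int dk = kk0; dk <= kk1; ++dk) {
          int ck = clampi(k + dk, n2);
          for (int dj = -radius; dj <= radius; ++dj) {
            int cj = clampi(j + dj, n1);
            for (int di = -radius; di <= radius; ++di) {
              int ci = clampi(i + di, n0);
              buf[m++] = x[ci + (R_xlen_t)n0 * (cj + (R_xlen_t)n1 * ck)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        double med = buf[m / 2];
        if (m % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
          med = 0.5 * (med + lo);
        }
        out[i + (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k)] = med;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// One pass of the exact 1D squared-distance transform (Felzenszwalb & Huttenlocher)
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in voxels) from each TRUE voxel to the
// nearest FALSE voxel centre. FALSE voxels get 0. All-TRUE input returns Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  int nd = dim.size();
  int n0 = dim[0], n1 = nd > 1 ? dim[1] : 1, n2 = nd > 2 ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)n0 * n1 * n2;
  NumericVector g(n);
  // large finite sentinel: infinities break the parabola intersections
  const double INF = 1e15;
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(n0, std::max(n1, n2));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 0
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j) {
      R_xlen_t base = (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k);
      for (int i = 0; i < n0; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, n0);
      for (int i = 0; i < n0; ++i) g[base + i] = d[i];
    }
  // axis 1
  if (n1 > 1)
    for (int k = 0; k < n2; ++k)
      for (int i = 0; i < n0; ++i) {
        for (int j = 0; j < n1; ++j)
          f[j] = g[i + (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k)];
        dt1d(f, d, v, z, n1);
        for (int j = 0; j < n1; ++j) g[i + (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k)] = d[j];
      }
  // axis 2
  if (n2 > 1)
    for (int j = 0; j < n1; ++j)
      for (int i = 0; i < n0; ++i) {
        for (int k = 0; k < n2; ++k)
          f[k] = g[i + (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k)];
        dt1d(f, d, v, z, n2);
        for (int k = 0; k < n2; ++k) g[i + (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k)] = d[k];
      }
  g.attr("dim") = dim;
  return g;
}

// Hildebrand-Ruegsegger local thickness by sphere painting. r2 holds the
// squared inscribed-sphere radius of every voxel of the phase (0 outside).
// Each voxel p receives 2*sqrt(max r2(c)) over centres c with |p-c|^2 < r2(c)
// (strict inequality; squared distances on the integer grid are integers).
// Spheres are clipped at the volume faces. Returns thickness in voxels.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector r2, IntegerVector dim) {
  int nd = dim.size();
  int n0 = dim[0], n1 = nd > 1 ? dim[1] : 1, n2 = nd > 2 ? dim[2] : 1;
  R_xlen_t n = (R_xlen_t)n0 * n1 * n2;
  NumericVector th2(n);
  // distance-ridge pruning: a centre whose sphere lies entirely inside a
  // neighbour's sphere (r_n >= r_c + |c-n|, with a conservative margin so
  // borderline cases are kept) contributes nothing and is skipped
  std::vector<double> r(n);
  for (R_xlen_t i = 0; i < n; ++i) r[i] = std::sqrt(r2[i]);
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j)
      for (int i = 0; i < n0; ++i) {
        double r2c = r2[i + (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k)];
        if (r2c <= 0) continue;
        double rc = r[i + (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k)];
        bool dominated = false;
        for (int dk = -1; dk <= 1 && !dominated; ++dk) {
          int nk = k + dk; if (nk < 0 || nk >= n2) continue;
          for (int dj = -1; dj <= 1 && !dominated; ++dj) {
            int nj = j + dj; if (nj < 0 || nj >= n1) continue;
            for (int di = -1; di <= 1; ++di) {
              int ni = i + di; if (ni < 0 || ni >= n0) continue;
              if (di == 0 && dj == 0 && dk == 0) continue;
              double rn = r[ni + (R_xlen_t)n0 * (nj + (R_xlen_t)n1 * nk)];
              double dist = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (rn >= rc + dist + 1e-9) { dominated = true; break; }
            }
          }
        }
        if (dominated) continue;
        int R = (int)std::floor(std::sqrt(r2c - 0.5) + 1e-9);
        int k0 = std::max(0, k - R), k1v = std::min(n2 - 1, k + R);
        int j0 = std::max(0, j - R), j1v = std::min(n1 - 1, j + R);
        int i0 = std::max(0, i - R), i1v = std::min(n0 - 1, i + R);
        for (int kk = k0; kk <= k1v; ++kk) {
          int dk = kk - k;
          for (int jj = j0; jj <= j1v; ++jj) {
            int dj = jj - j;
            int d2kj = dk * dk + dj * dj;
            for (int ii = i0; ii <= i1v; ++ii) {
              int di = ii - i;
              double d2 = d2kj + di * di;
              if (d2 + 0.5 < r2c) {
                R_xlen_t idx = ii + (R_xlen_t)n0 * (jj + (R_xlen_t)n1 * kk);
                if (r2c > th2[idx]) th2[idx] = r2c;
              }
            }
          }
        }
      }
  for (R_xlen_t i = 0; i < n; ++i) th2[i] = 2.0 * std::sqrt(th2[i]);
  th2.attr("dim") = dim;
  return th2;
}

// Scatter-add: out[idx[i]] += v[i] (1-based idx), the col2im accumulation.
// [[Rcpp::export]]
NumericVector cpp_scatter_add(NumericVector v, IntegerVector idx, int n) {
  NumericVector out(n);
  R_xlen_t m = v.size();
  for (R_xlen_t i = 0; i < m; ++i) out[idx[i] - 1] += v[i];
  return out;
}
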