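#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas), weight w2 =
// squared grid step along this axis. f holds squared distances on input.
static void dt1d(std::vector<double> &f, std::vector<double> &d, double w2,
                 double big) {
  const int n = (int)f.size();
  if (n == 1) { d[0] = f[0]; return; }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -big;
  z[1] = big;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = big;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = (double)q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform on an anisotropic grid: for every
// foreground voxel, the physical distance to the nearest background voxel
// centre; 0 on background. dim = (n1, n2, n3), spacing in mm per axis.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  double ext = 0.0;
  for (int a = 0; a < 3; ++a) {
    double e = spacing[a] * dim[a];
    ext += e * e;
  }
  const double big = 4.0 * ext + 1.0;
  std::vector<double> D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? big : 0.0;

  std::vector<double> f, d;
  // axis 1 (fastest varying)
  f.resize(n1); d.resize(n1);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t off = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; ++i) f[i] = D[off + i];
      dt1d(f, d, spacing[0] * spacing[0], big);
      for (int i = 0; i < n1; ++i) D[off + i] = d[i];
    }
  // axis 2
  f.resize(n2); d.resize(n2);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; ++j) f[j] = D[base + (R_xlen_t)n1 * j];
      dt1d(f, d, spacing[1] * spacing[1], big);
      for (int j = 0; j < n2; ++j) D[base + (R_xlen_t)n1 * j] = d[j];
    }
  // axis 3
  if (n3 > 1) {
    f.resize(n3); d.resize(n3);
    const R_xlen_t plane = (R_xlen_t)n1 * n2;
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t base = i + (R_xlen_t)n1 * j;
        for (int k = 0; k < n3; ++k) f[k] = D[base + plane * k];
        dt1d(f, d, spacing[2] * spacing[2], big);
        for (int k = 0; k < n3; ++k) D[base + plane * k] = d[k];
      }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = D[i] >= big ? R_PosInf : std::sqrt(D[i]);
  return out;
}
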