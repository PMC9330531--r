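#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Squared Euclidean distance transform, separable lower-envelope algorithm
// (Felzenszwalb & Huttenlocher 2012), generalized to anisotropic sample
// spacing. Distances are physical (micrometres) to the nearest feature
// (TRUE) voxel. BIG stands in for +Inf so the parabola intersections stay
// finite.

static const double BIG = 1e30;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double h2) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s <= z[k]) {
        k--;
      } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    int p = v[k];
    d[q] = h2 * (double)(q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; i++) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest varying)
  double h2 = spacing[0] * spacing[0];
  for (int k = 0; k < n3; k++) {
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; i++) f[i] = out[base + i];
      dt1d(f, d, v, z, n1, h2);
      for (int i = 0; i < n1; i++) out[base + i] = d[i];
    }
  }
  // axis 2
  h2 = spacing[1] * spacing[1];
  for (int k = 0; k < n3; k++) {
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; j++) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f, d, v, z, n2, h2);
      for (int j = 0; j < n2; j++) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  }
  // axis 3
  h2 = spacing[2] * spacing[2];
  for (int j = 0; j < n2; j++) {
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * j;
      R_xlen_t stride = (R_xlen_t)n1 * n2;
      for (int k = 0; k < n3; k++) f[k] = out[base + stride * k];
      dt1d(f, d, v, z, n3, h2);
      for (int k = 0; k < n3; k++) out[base + stride * k] = d[k];
    }
  }

  for (R_xlen_t i = 0; i < ntot; i++) {
    out[i] = (out[i] >= BIG) ? R_PosInf : std::sqrt(out[i]);
  }
  return out;
}
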