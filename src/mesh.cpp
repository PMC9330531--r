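#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Surface meshing of a voxel region by marching tetrahedra on the scalar
// field of voxel values (optionally Gaussian-smoothed first, see R side).
// Each grid cell is split into six tetrahedra around the main diagonal
// (Kuhn triangulation, translation-consistent so the mesh is crack-free);
// iso-surface vertices are placed by linear interpolation along tet edges.
// Returns total triangle area and the signed enclosed volume computed by
// the divergence theorem, with triangles oriented outward.

struct V3 { double x, y, z; };

static inline V3 sub(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double norm(V3 a) { return std::sqrt(dot(a, a)); }

static inline V3 lerp(V3 a, V3 b, double fa, double fb, double iso) {
  double t = (iso - fa) / (fb - fa);
  return {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
}

// accumulate one outward-oriented triangle
static void add_tri(V3 p1, V3 p2, V3 p3, V3 inward, double& area, double& vol) {
  V3 n = cross(sub(p2, p1), sub(p3, p1));
  double a2 = norm(n);
  if (a2 <= 0) return;
  // orient outward: normal must point away from the inside reference point
  if (dot(n, sub(p1, inward)) < 0) { V3 tmp = p2; p2 = p3; p3 = tmp; n.x = -n.x; n.y = -n.y; n.z = -n.z; }
  area += 0.5 * a2;
  vol += (p1.x * (p2.y * p3.z - p3.y * p2.z)
        - p2.x * (p1.y * p3.z - p3.y * p1.z)
        + p3.x * (p1.y * p2.z - p2.y * p1.z)) / 6.0;
}

// [[Rcpp::export(name = ".mesh_measure_cpp")]]
NumericVector mesh_measure_cpp(NumericVector field, IntegerVector dim,
                               NumericVector spacing, double iso) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  double area = 0.0, vol = 0.0;

  // field value with one layer of background (0) padding outside the grid
  auto F = [&](int i, int j, int k) -> double {
    if (i < 0 || j < 0 || k < 0 || i >= n1 || j >= n2 || k >= n3) return 0.0;
    return field[(R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
  };

  // cube corner offsets, index bit 0 -> +i, bit 1 -> +j, bit 2 -> +k
  static const int co[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
  };
  // Kuhn decomposition: six tets sharing the main diagonal 0-7
  static const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}
  };

  double f[8];
  V3 p[8];
  for (int k = -1; k < n3; k++)
    for (int j = -1; j < n2; j++)
      for (int i = -1; i < n1; i++) {
        int nin = 0;
        for (int c = 0; c < 8; c++) {
          int ci = i + co[c][0], cj = j + co[c][1], ck = k + co[c][2];
          f[c] = F(ci, cj, ck);
          p[c] = {ci * s1, cj * s2, ck * s3};
          if (f[c] > iso) nin++;
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; t++) {
          int vin[4], vout[4], ni = 0, no = 0;
          for (int v = 0; v < 4; v++) {
            int c = tets[t][v];
            if (f[c] > iso) vin[ni++] = c; else vout[no++] = c;
          }
          if (ni == 0 || ni == 4) continue;
          // reference inside point for orientation
          V3 inw = {0, 0, 0};
          for (int v = 0; v < ni; v++) {
            inw.x += p[vin[v]].x / ni; inw.y += p[vin[v]].y / ni; inw.z += p[vin[v]].z / ni;
          }
          if (ni == 1) {
            V3 a = lerp(p[vin[0]], p[vout[0]], f[vin[0]], f[vout[0]], iso);
            V3 b = lerp(p[vin[0]], p[vout[1]], f[vin[0]], f[vout[1]], iso);
            V3 c = lerp(p[vin[0]], p[vout[2]], f[vin[0]], f[vout[2]], iso);
            add_tri(a, b, c, inw, area, vol);
          } else if (ni == 3) {
            V3 a = lerp(p[vin[0]], p[vout[0]], f[vin[0]], f[vout[0]], iso);
            V3 b = lerp(p[vin[1]], p[vout[0]], f[vin[1]], f[vout[0]], iso);
            V3 c = lerp(p[vin[2]], p[vout[0]], f[vin[2]], f[vout[0]], iso);
            add_tri(a, b, c, inw, area, vol);
          } else { // ni == 2: quad split into two triangles
            V3 a = lerp(p[vin[0]], p[vout[0]], f[vin[0]], f[vout[0]], iso);
            V3 b = lerp(p[vin[0]], p[vout[1]], f[vin[0]], f[vout[1]], iso);
            V3 c = lerp(p[vin[1]], p[vout[1]], f[vin[1]], f[vout[1]], iso);
            V3 d = lerp(p[vin[1]], p[vout[0]], f[vin[1]], f[vout[0]], iso);
            add_tri(a, b, c, inw, area, vol);
            add_tri(a, c, d, inw, area, vol);
          }
        }
      }

  return NumericVector::create(area, std::fabs(vol));
}

// Separable Gaussian smoothing (sigma in voxel units per axis, kernel
// truncated at 3 sigma, zero padding). Used to relax the voxel staircase
// before meshing.
// [[Rcpp::export(name = ".smooth3d_cpp")]]
NumericVector smooth3d_cpp(NumericVector field, IntegerVector dim,
                           NumericVector sigma) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t ntot = (R_xlen_t)n[0] * n[1] * n[2];
  std::vector<double> a(field.begin(), field.end()), b(ntot);

  R_xlen_t stride[3] = {1, (R_xlen_t)n[0], (R_xlen_t)n[0] * n[1]};

  for (int ax = 0; ax < 3; ax++) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; t++) { ker[t + r] = std::exp(-0.5 * t * t / (s * s)); tot += ker[t + r]; }
    for (int t = 0; t <= 2 * r; t++) ker[t] /= tot;

    int o1 = (ax + 1) % 3, o2 = (ax + 2) % 3;
    for (int u = 0; u < n[o1]; u++)
      for (int v = 0; v < n[o2]; v++) {
        R_xlen_t base = stride[o1] * u + stride[o2] * v;
        for (int q = 0; q < n[ax]; q++) {
          double acc = 0;
          for (int t = -r; t <= r; t++) {
            int qq = q + t;
            if (qq < 0 || qq >= n[ax]) continue; // zero padding
            acc += ker[t + r] * a[base + stride[ax] * qq];
          }
          b[base + stride[ax] * q] = acc;
        }
      }
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}
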