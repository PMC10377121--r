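#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact Euclidean distance transform, separable lower-envelope algorithm
// (Felzenszwalb & Huttenlocher), extended to anisotropic voxel spacing by
// working in physical (mm) coordinates along each axis.

static const double BIG = 1e30; // finite stand-in for +inf; keeps parabola
                                // intersections well defined

// One 1D pass: g holds squared distances along a line with sample positions
// q*step; overwritten with the lower envelope evaluated at each sample.
static void edt_pass_1d(std::vector<double>& g, int n, double step,
                        std::vector<double>& f, std::vector<int>& v,
                        std::vector<double>& z) {
  for (int i = 0; i < n; ++i) f[i] = g[i];
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s;
    for (;;) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) {
        --k;
      } else if (s <= z[k]) { // k == 0: parabola q dominates everywhere
        v[0] = q;
        z[0] = -BIG;
        z[1] = BIG;
        s = NA_REAL;
        break;
      } else {
        break;
      }
    }
    if (!ISNA(s)) {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = BIG;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * step;
    g[q] = dx * dx + f[v[k]];
  }
}

// Distance (mm) from every voxel to the nearest site voxel (sites[i] != 0).
// Voxels are indexed column-major with dims dim, physical spacing per axis.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector sites, IntegerVector dim,
                      NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nt = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> g(nt);
  for (R_xlen_t i = 0; i < nt; ++i) g[i] = sites[i] ? 0.0 : BIG;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> line(nmax), f(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; ++i) line[i] = g[base + i];
      edt_pass_1d(line, n1, spacing[0], f, v, z);
      for (int i = 0; i < n1; ++i) g[base + i] = line[i];
    }
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * (R_xlen_t)k;
      for (int j = 0; j < n2; ++j) line[j] = g[base + (R_xlen_t)n1 * j];
      edt_pass_1d(line, n2, spacing[1], f, v, z);
      for (int j = 0; j < n2; ++j) g[base + (R_xlen_t)n1 * j] = line[j];
    }
  const R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * j;
      for (int k = 0; k < n3; ++k) line[k] = g[base + plane * k];
      edt_pass_1d(line, n3, spacing[2], f, v, z);
      for (int k = 0; k < n3; ++k) g[base + plane * k] = line[k];
    }

  NumericVector out(nt);
  for (R_xlen_t i = 0; i < nt; ++i)
    out[i] = (g[i] >= BIG) ? R_PosInf : std::sqrt(g[i]);
  return out;
}
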