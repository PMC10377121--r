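#include <Rcpp.h>
#include "stamping.h"
#include <vector>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// Stamp a precomputed sphere-offset template at each center (0-based i,j,k
// rows), clipping at the volume boundary. Returns the per-voxel count of
// contributing centers.
// [[Rcpp::export]]
IntegerVector cpp_count_map(IntegerVector dim, IntegerMatrix offsets,
                            IntegerMatrix centers) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nt = (R_xlen_t)n1 * n2 * n3;
  OffsetTemplate tpl(offsets, dim);
  IntegerVector counts(nt, 0);
  int* cp = INTEGER(counts);
  for (int c = 0; c < centers.nrow(); ++c)
    tpl.stamp(cp, centers(c, 0), centers(c, 1), centers(c, 2));
  return counts;
}

// Accumulate, over n_sims simulated center sets, the per-voxel histogram of
// sphere counts. Row r (0-based) of the result holds, for each voxel, how
// many simulations produced count == r. Simulated maps are never stored.
// [[Rcpp::export]]
IntegerMatrix cpp_null_count_histogram(IntegerVector dim,
                                       IntegerMatrix offsets,
                                       IntegerMatrix centers, int n_sims,
                                       int n_centers) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nt = (R_xlen_t)n1 * n2 * n3;
  OffsetTemplate tpl(offsets, dim);
  IntegerMatrix hist(n_centers + 1, (int)nt);
  int* hp = INTEGER(hist);
  const int nr = n_centers + 1;
  const int* ce = INTEGER(centers);
  const R_xlen_t crows = centers.nrow();
  std::vector<int> counts(nt, 0);
  for (int s = 0; s < n_sims; ++s) {
    std::memset(&counts[0], 0, nt * sizeof(int));
    for (int c = 0; c < n_centers; ++c) {
      R_xlen_t r = (R_xlen_t)s * n_centers + c;
      tpl.stamp(&counts[0], ce[r], ce[r + crows], ce[r + 2 * crows]);
    }
    for (R_xlen_t v = 0; v < nt; ++v) ++hp[counts[v] + nr * v];
  }
  return hist;
}

// Per-voxel empirical quantile from a count histogram (rows = count values
// 0..K, columns = voxels). type 5: linear interpolation between order
// statistics at positions (h - 0.5)/n (the convention used by Matlab's
// quantile). type 0: conservative ceiling rank.
// [[Rcpp::export]]
NumericVector cpp_quantile_from_counts(IntegerMatrix hist, double prob,
                                       int type) {
  const int K = hist.nrow() - 1;
  const int nv = hist.ncol();
  NumericVector out(nv);
  for (int v = 0; v < nv; ++v) {
    double n = 0;
    for (int r = 0; r <= K; ++r) n += hist(r, v);
    if (n == 0) {
      out[v] = NA_REAL;
      continue;
    }
    if (type == 0) {
      double target = std::ceil(n * prob);
      if (target < 1) target = 1;
      double cum = 0;
      int q = K;
      for (int r = 0; r <= K; ++r) {
        cum += hist(r, v);
        if (cum >= target) {
          q = r;
          break;
        }
      }
      out[v] = (double)q;
      continue;
    }
    double h = n * prob + 0.5;
    if (h <= 1.0) h = 1.0;
    if (h >= n) h = n;
    double j = std::floor(h);
    double gamma = h - j;
    // x_(j) and x_(j+1), 1-based order statistics
    double cum = 0;
    double xj = K, xj1 = K;
    bool found_j = false;
    for (int r = 0; r <= K; ++r) {
      cum += hist(r, v);
      if (!found_j && cum >= j) {
        xj = r;
        found_j = true;
      }
      if (cum >= j + 1) {
        xj1 = r;
        break;
      }
    }
    if (gamma == 0.0 || j >= n)
      out[v] = xj;
    else
      out[v] = xj + gamma * (xj1 - xj);
  }
  return out;
}
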