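#ifndef LESIONMAP_STAMPING_H
#define LESIONMAP_STAMPING_H

#include <Rcpp.h>
#include <vector>
#include <cstdlib>

// Precomputed sphere-offset template: raw per-axis offsets plus linear
// offsets for the fast interior path (no bounds checks needed when the
// center is at least the template's reach away from every face).
struct OffsetTemplate {
  int n1, n2, n3;
  int K;
  std::vector<int> di, dj, dk;
  std::vector<R_xlen_t> lin;
  int r1, r2, r3; // per-axis reach

  OffsetTemplate(const Rcpp::IntegerMatrix& offsets,
                 const Rcpp::IntegerVector& dim) {
    n1 = dim[0];
    n2 = dim[1];
    n3 = dim[2];
    K = offsets.nrow();
    di.resize(K);
    dj.resize(K);
    dk.resize(K);
    lin.resize(K);
    r1 = r2 = r3 = 0;
    for (int t = 0; t < K; ++t) {
      di[t] = offsets(t, 0);
      dj[t] = offsets(t, 1);
      dk[t] = offsets(t, 2);
      lin[t] = di[t] + (R_xlen_t)n1 * (dj[t] + (R_xlen_t)n2 * dk[t]);
      if (std::abs(di[t]) > r1) r1 = std::abs(di[t]);
      if (std::abs(dj[t]) > r2) r2 = std::abs(dj[t]);
      if (std::abs(dk[t]) > r3) r3 = std::abs(dk[t]);
    }
  }

  // Add 1 to counts at every template position around (ci,cj,ck).
  inline void stamp(int* counts, int ci, int cj, int ck) const {
    if (ci >= r1 && cj >= r2 && ck >= r3 && ci < n1 - r1 && cj < n2 - r2 &&
        ck < n3 - r3) {
      R_xlen_t base = ci + (R_xlen_t)n1 * (cj + (R_xlen_t)n2 * ck);
      for (int t = 0; t < K; ++t) ++counts[base + lin[t]];
    } else {
      for (int t = 0; t < K; ++t) {
        int ii = ci + di[t], jj = cj + dj[t], kk = ck + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
          continue;
        ++counts[ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk)];
      }
    }
  }
};

#endif
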