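#include <Rcpp.h>
#include "stamping.h"
#include <vector>
#include <array>
#include <cstring>
#include <cmath>
using namespace Rcpp;

static std::vector<std::array<int, 3> > neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3> > off;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj && !dk) continue;
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        std::array<int, 3> o = {{di, dj, dk}};
        off.push_back(o);
      }
  return off;
}

// Label connected components among a sparse set of voxels (0-based linear
// indices into a dim-shaped array). Returns 1-based component labels parallel
// to `voxels`.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector dim, IntegerVector voxels,
                                   int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nt = (R_xlen_t)n1 * n2 * n3;
  const R_xlen_t nv = voxels.size();
  IntegerVector labels(nv, 0);
  if (nv == 0) return labels;

  std::vector<int> pos(nt, -1); // voxel -> index into `voxels`
  for (R_xlen_t m = 0; m < nv; ++m) pos[voxels[m]] = (int)m;

  std::vector<std::array<int, 3> > off = neighbor_offsets(connectivity);
  std::vector<int> stack;
  int next_label = 0;
  for (R_xlen_t m = 0; m < nv; ++m) {
    if (labels[m]) continue;
    ++next_label;
    labels[m] = next_label;
    stack.clear();
    stack.push_back((int)m);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      R_xlen_t lin = voxels[cur];
      int i = (int)(lin % n1);
      int j = (int)((lin / n1) % n2);
      int k = (int)(lin / ((R_xlen_t)n1 * n2));
      for (size_t t = 0; t < off.size(); ++t) {
        int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
          continue;
        R_xlen_t nb = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        int pm = pos[nb];
        if (pm >= 0 && !labels[pm]) {
          labels[pm] = next_label;
          stack.push_back(pm);
        }
      }
    }
  }
  return labels;
}

// Fill interior cavities of a binary mask: background voxels (value 0) not
// 6-connected to the array border become foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes(IntegerVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nt = (R_xlen_t)n1 * n2 * n3;
  std::vector<char> outside(nt, 0);
  std::vector<R_xlen_t> stack;

  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        if (i && j && k && i != n1 - 1 && j != n2 - 1 && k != n3 - 1) continue;
        R_xlen_t lin = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        if (!mask[lin] && !outside[lin]) {
          outside[lin] = 1;
          stack.push_back(lin);
        }
      }
  const int d1[6] = {1, -1, 0, 0, 0, 0};
  const int d2[6] = {0, 0, 1, -1, 0, 0};
  const int d3[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    R_xlen_t lin = stack.back();
    stack.pop_back();
    int i = (int)(lin % n1);
    int j = (int)((lin / n1) % n2);
    int k = (int)(lin / ((R_xlen_t)n1 * n2));
    for (int t = 0; t < 6; ++t) {
      int ii = i + d1[t], jj = j + d2[t], kk = k + d3[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
        continue;
      R_xlen_t nb = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
      if (!mask[nb] && !outside[nb]) {
        outside[nb] = 1;
        stack.push_back(nb);
      }
    }
  }
  IntegerVector out(nt);
  for (R_xlen_t i = 0; i < nt; ++i) out[i] = mask[i] ? 1 : (outside[i] ? 0 : 1);
  return out;
}

// Null-map simulation loop used for cluster-size calibration and for
// empirical checks of the fitted thresholds. For each of n_sims simulated
// center sets, stamps the sphere kernel, then over in-mask voxels counts
// strict exceedances of thr_counts and labels the exceedance set into
// connected components. Returns per-map exceedance counts, all cluster sizes
// pooled across maps, the per-map number of clusters, and the per-map
// maximum cluster size (0 when none).
// [[Rcpp::export]]
List cpp_null_cluster_stats(IntegerVector dim, IntegerMatrix offsets,
                            IntegerMatrix centers, int n_sims, int n_centers,
                            NumericVector thr_counts, IntegerVector mask,
                            int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nt = (R_xlen_t)n1 * n2 * n3;
  OffsetTemplate tpl(offsets, dim);
  const int* ce = INTEGER(centers);
  const R_xlen_t crows = centers.nrow();
  const double* tp = REAL(thr_counts);

  std::vector<R_xlen_t> mask_vox;
  for (R_xlen_t i = 0; i < nt; ++i)
    if (mask[i]) mask_vox.push_back(i);

  std::vector<int> counts(nt, 0);
  std::vector<char> cand(nt, 0);
  std::vector<R_xlen_t> sup;
  std::vector<int> stack;
  std::vector<std::array<int, 3> > off = neighbor_offsets(connectivity);

  IntegerVector per_map_exceed(n_sims);
  IntegerVector per_map_nclus(n_sims);
  IntegerVector per_map_max(n_sims);
  std::vector<int> pooled_sizes;

  for (int s = 0; s < n_sims; ++s) {
    std::memset(&counts[0], 0, nt * sizeof(int));
    for (int c = 0; c < n_centers; ++c) {
      R_xlen_t r = (R_xlen_t)s * n_centers + c;
      tpl.stamp(&counts[0], ce[r], ce[r + crows], ce[r + 2 * crows]);
    }
    sup.clear();
    for (size_t m = 0; m < mask_vox.size(); ++m) {
      R_xlen_t v = mask_vox[m];
      if ((double)counts[v] > tp[v]) {
        sup.push_back(v);
        cand[v] = 1;
      }
    }
    per_map_exceed[s] = (int)sup.size();

    int nclus = 0, maxsz = 0;
    for (size_t m = 0; m < sup.size(); ++m) {
      R_xlen_t v = sup[m];
      if (cand[v] != 1) continue; // already claimed by a component
      int size = 0;
      cand[v] = 2;
      stack.clear();
      stack.push_back((int)m);
      // depth-first over the suprathreshold set
      std::vector<R_xlen_t> frontier;
      frontier.push_back(v);
      while (!frontier.empty()) {
        R_xlen_t cur = frontier.back();
        frontier.pop_back();
        ++size;
        int i = (int)(cur % n1);
        int j = (int)((cur / n1) % n2);
        int k = (int)(cur / ((R_xlen_t)n1 * n2));
        for (size_t t = 0; t < off.size(); ++t) {
          int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
            continue;
          R_xlen_t nb = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
          if (cand[nb] == 1) {
            cand[nb] = 2;
            frontier.push_back(nb);
          }
        }
      }
      ++nclus;
      if (size > maxsz) maxsz = size;
      pooled_sizes.push_back(size);
    }
    per_map_nclus[s] = nclus;
    per_map_max[s] = maxsz;
    for (size_t m = 0; m < sup.size(); ++m) cand[sup[m]] = 0;
  }

  return List::create(
      Named("per_map_exceed") = per_map_exceed,
      Named("per_map_n_clusters") = per_map_nclus,
      Named("per_map_max_size") = per_map_max,
      Named("pooled_sizes") =
          IntegerVector(pooled_sizes.begin(), pooled_sizes.end()),
      Named("n_mask_voxels") = (double)mask_vox.size());
}
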