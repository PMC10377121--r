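#!/usr/bin/env Rscript
# Stage 4: Monte-Carlo null calibration (per-voxel quantile thresholds and
# the cluster-size threshold) and the significant-cluster report per group.

source("analysis/common.R")

parenchyma <- read_volume(file.path(results_dir, "parenchyma.nii.gz"))
metrics <- read.csv(file.path(results_dir, "metrics.csv"))

reports <- list()
for (grp in sort(unique(metrics$group))) {
  rows <- metrics[metrics$group == grp, ]
  centers <- as.matrix(rows[, c("center_i", "center_j", "center_k")])
  fm <- build_frequency_map(centers, radius_mm, parenchyma, group = grp)
  thr <- estimate_voxel_thresholds(fm$n_tumors, parenchyma, radius_mm,
                                   inference_config)
  cn <- calibrate_cluster_threshold(fm$n_tumors, parenchyma, radius_mm, thr,
                                    inference_config)
  clusters <- find_significant_clusters(fm, thr, cn, parenchyma)
  reports[[grp]] <- cluster_report(clusters, group = grp)
  write_volume(thr$grid, file.path(results_dir,
                                   sprintf("thr_%s.nii.gz", grp)))
  cat(sprintf(
    "%s: cluster-size threshold %d voxels; %d significant cluster(s)\n",
    grp, cn$cluster_size_threshold, length(clusters)))
}

tab <- do.call(rbind, reports)
write.csv(tab, file.path(results_dir, "clusters.csv"), row.names = FALSE)
print(tab, row.names = FALSE)
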