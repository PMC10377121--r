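#!/usr/bin/env Rscript
# Stage 3: per-group tumor frequency maps from the 20-mm sphere kernel, plus
# pairwise difference maps.

source("analysis/common.R")

parenchyma <- read_volume(file.path(results_dir, "parenchyma.nii.gz"))
metrics <- read.csv(file.path(results_dir, "metrics.csv"))

groups <- sort(unique(metrics$group))
maps <- list()
for (grp in groups) {
  rows <- metrics[metrics$group == grp, ]
  centers <- as.matrix(rows[, c("center_i", "center_j", "center_k")])
  maps[[grp]] <- build_frequency_map(centers, radius_mm, parenchyma,
                                     group = grp)
  write_volume(maps[[grp]]$grid,
               file.path(results_dir, sprintf("freq_%s.nii.gz", grp)))
  cat(sprintf("%s: %d tumors, peak frequency %.3f\n", grp,
              maps[[grp]]$n_tumors, max(maps[[grp]]$grid$values)))
}

pairs <- combn(groups, 2)
for (i in seq_len(ncol(pairs))) {
  a <- pairs[1, i]; b <- pairs[2, i]
  dm <- difference_map(maps[[a]], maps[[b]])
  write_volume(dm, file.path(results_dir,
                             sprintf("diff_%s_minus_%s.nii.gz", a, b)))
}
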