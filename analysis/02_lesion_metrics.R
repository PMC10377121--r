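#!/usr/bin/env Rscript
# Stage 2: rebuild the parenchymal mask from the tissue probability maps and
# compute per-lesion metrics (center, depth, GMD, volumes).

source("analysis/common.R")

gm <- read_volume(file.path(cohort_dir, "gm.nii.gz"))
wm <- read_volume(file.path(cohort_dir, "wm.nii.gz"))
records <- read_cohort(file.path(cohort_dir, "cohort.csv"))

parenchyma <- build_parenchyma_mask(gm, wm)
write_volume(parenchyma, file.path(results_dir, "parenchyma.nii.gz"))

metrics <- compute_lesion_metrics(records, parenchyma, gm)
write.csv(metrics, file.path(results_dir, "metrics.csv"), row.names = FALSE)

gmd_hist <- gmd_distribution(metrics$gmd_at_center)
cat(sprintf("parenchyma: %d voxels; %d lesions; GMD peak bin center %.2f\n",
            sum(parenchyma$values), nrow(metrics),
            gmd_hist$peak_bin_center))
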