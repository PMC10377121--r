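#!/usr/bin/env Rscript
# Stage 1: generate the synthetic phantom and the three-group lesion cohort,
# and write them in the on-disk layout the later stages consume.

source("analysis/common.R")

phantom <- make_phantom(phantom_settings)

cohorts <- lapply(seq_along(group_specs), function(i) {
  grp <- names(group_specs)[i]
  sample_cohort(group_specs[[grp]](master_seed + i), phantom)
})
records <- do.call(c, lapply(cohorts, `[[`, "records"))
ground_truth <- do.call(rbind, lapply(cohorts, `[[`, "ground_truth"))

# each sample_cohort() call numbers its lesions from 1, so relabel with
# globally unique ids before writing to a shared directory
new_ids <- sprintf("les%05d", seq_along(records))
for (i in seq_along(records)) records[[i]]$lesion_id <- new_ids[i]
ground_truth$lesion_id <- new_ids

combined <- list(records = records, ground_truth = ground_truth)
cohort_to_disk(combined, phantom, cohort_dir)

cat(sprintf("wrote %d lesions (%s) to %s\n", length(records),
            paste(sprintf("%s: %d", names(group_specs),
                          table(ground_truth$group)[names(group_specs)]),
                  collapse = ", "),
            cohort_dir))
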