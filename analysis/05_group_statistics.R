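#!/usr/bin/env Rscript
# Stage 5: per-group descriptive summaries and rank-based group comparisons
# of the lesion features.

source("analysis/common.R")

metrics <- read.csv(file.path(results_dir, "metrics.csv"))
cmp <- compare_groups(metrics)

write.csv(cmp$summary, file.path(results_dir, "feature_summary.csv"),
          row.names = FALSE)
write.csv(cmp$omnibus, file.path(results_dir, "omnibus_tests.csv"),
          row.names = FALSE)
write.csv(cmp$pairwise, file.path(results_dir, "pairwise_tests.csv"),
          row.names = FALSE)

cat("omnibus tests:\n")
print(cmp$omnibus, row.names = FALSE)
cat("\npairwise Kruskal-Wallis (unadjusted and Holm):\n")
print(cmp$pairwise, row.names = FALSE)
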