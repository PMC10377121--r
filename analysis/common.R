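# Shared settings for the numbered analysis drivers. Source this file from
# each script; all paths are relative to the repository root.

library(lesionmap)

results_dir <- "results"
cohort_dir <- file.path(results_dir, "cohort")
dir.create(results_dir, showWarnings = FALSE)

master_seed <- 20240601L

# Synthetic brain: 48^3 grid at 2 mm with an ellipsoidal ventricle, so the
# mask-building stage exercises hole filling.
phantom_settings <- phantom_spec(
  shape = c(48L, 48L, 48L), voxel_size_mm = 2,
  semi_axes_mm = c(40, 44, 36),
  ventricle = list(semi_axes_mm = c(10, 14, 8), offset_mm = c(0, 4, 2)))

# One cohort spec per mutation group, sharing patient counts and lesion-size
# model but differing in spatial placement: EGFR concentrates around a
# planted hotspot, ALK sits on the gray/white junction, KRAS is uniform.
hotspot_mm <- matrix(c(20, -15, 5), 1)
group_specs <- list(
  EGFR = function(seed) cohort_spec(
    groups = list(EGFR = list(n_patients = 10L,
                              tumors_per_patient = c(5L, 30L))),
    placement = "hotspot_mixture", hotspot_centers_mm = hotspot_mm,
    concentration_mm = 8, mixing_fraction = 0.8, seed = seed),
  ALK = function(seed) cohort_spec(
    groups = list(ALK = list(n_patients = 10L,
                             tumors_per_patient = c(5L, 30L))),
    placement = "junction", seed = seed),
  KRAS = function(seed) cohort_spec(
    groups = list(KRAS = list(n_patients = 10L,
                              tumors_per_patient = c(5L, 30L))),
    placement = "uniform", seed = seed))

radius_mm <- 20
inference_config <- null_config(n_voxel_sims = 2000L, n_cluster_sims = 5000L,
                                voxel_p = 0.001, cluster_p = 0.05,
                                connectivity = 26L, seed = master_seed)
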