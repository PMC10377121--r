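#' Run the full lesion-mapping pipeline
#'
#' Orchestrates the stages on one cohort: parenchymal mask construction from
#' the tissue probability maps, per-lesion metrics, per-group frequency maps,
#' per-group Monte-Carlo null calibration and cluster reports (each group's
#' null is calibrated with that group's own tumor count), and the group
#' comparison tables. A manifest recording seeds, parameters and input
#' fingerprints is returned and written alongside the outputs; re-running
#' with the same inputs and config reproduces identical cluster reports.
#'
#' @param records List of [lesion_record()]s (e.g. from [sample_cohort()] or
#'   [read_cohort()]).
#' @param gm,wm Tissue probability maps (`volume_grid`s).
#' @param output_dir Output directory, or `NULL` to skip writing.
#' @param params [parenchyma_params()] for mask construction.
#' @param radius_mm Frequency-map sphere radius (mm).
#' @param config [null_config()] for the inference stage.
#' @param groups Group labels to analyze (default: all present).
#' @param write_maps Also write frequency/threshold maps as NIfTI.
#' @return List with `parenchyma`, `metrics`, `frequency_maps`, `clusters`
#'   (per-group cluster report data.frame), `group_stats`, `manifest`.
#' @export
run_pipeline <- function(records, gm, wm, output_dir = NULL,
                         params = parenchyma_params(), radius_mm = 20,
                         config = null_config(), groups = NULL,
                         write_maps = FALSE) {
  assert_compatible(list(gm, wm))
  parenchyma <- build_parenchyma_mask(gm, wm, params)
  metrics <- compute_lesion_metrics(records, parenchyma, gm)
  if (is.null(groups)) groups <- sort(unique(metrics$group))

  freq_maps <- list()
  reports <- list()
  for (grp in groups) {
    gm_rows <- metrics[metrics$group == grp, , drop = FALSE]
    if (nrow(gm_rows) == 0L)
      lm_abort(sprintf("stage freqmap: no lesions in group %s", grp),
               "lesionmap_error_unknown_group")
    centers <- as.matrix(gm_rows[, c("center_i", "center_j", "center_k")])
    fm <- build_frequency_map(centers, radius_mm, parenchyma, group = grp)
    thr <- estimate_voxel_thresholds(fm$n_tumors, parenchyma, radius_mm,
                                     config)
    cn <- calibrate_cluster_threshold(fm$n_tumors, parenchyma, radius_mm,
                                      thr, config)
    cl <- find_significant_clusters(fm, thr, cn, parenchyma)
    freq_maps[[grp]] <- fm
    reports[[grp]] <- cluster_report(cl, group = grp)
    if (!is.null(output_dir) && write_maps) {
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
      write_volume(fm$grid,
                   file.path(output_dir, sprintf("freq_%s.nii.gz", grp)))
      write_volume(thr$grid,
                   file.path(output_dir, sprintf("thr_%s.nii.gz", grp)))
    }
  }
  cluster_tab <- do.call(rbind, reports)
  gstats <- compare_groups(metrics)

  manifest <- list(
    package_version = as.character(utils::packageVersion("lesionmap")),
    seed = config$seed,
    n_voxel_sims = config$n_voxel_sims,
    n_cluster_sims = config$n_cluster_sims,
    voxel_p = config$voxel_p, cluster_p = config$cluster_p,
    connectivity = config$connectivity,
    calibration_rule = config$calibration_rule,
    quantile_type = config$quantile_type,
    radius_mm = radius_mm,
    probability_threshold = params$probability_threshold,
    closing_radius_mm = params$closing_radius_mm,
    groups = groups,
    n_lesions = length(records),
    gm_fingerprint = grid_fingerprint(gm),
    wm_fingerprint = grid_fingerprint(wm),
    parenchyma_fingerprint = grid_fingerprint(parenchyma)
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(output_dir, "metrics.csv"),
              row.names = FALSE)
    write.csv(cluster_tab, file.path(output_dir, "clusters.csv"),
              row.names = FALSE)
    write.csv(gstats$summary, file.path(output_dir, "feature_summary.csv"),
              row.names = FALSE)
    write.csv(gstats$omnibus, file.path(output_dir, "omnibus_tests.csv"),
              row.names = FALSE)
    write.csv(gstats$pairwise, file.path(output_dir, "pairwise_tests.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (write_maps)
      write_volume(parenchyma, file.path(output_dir, "parenchyma.nii.gz"))
  }
  list(parenchyma = parenchyma, metrics = metrics,
       frequency_maps = freq_maps, clusters = cluster_tab,
       group_stats = gstats, manifest = manifest)
}
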