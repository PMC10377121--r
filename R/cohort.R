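#' Synthetic lesion cohort specification
#'
#' Describes a cohort of roughly spherical lesions grouped by patient and
#' mutation group, with a configurable spatial placement model: `"uniform"`
#' (centers uniform over the parenchyma), `"junction"` (centers on the
#' gray/white junction band), or `"hotspot_mixture"` (a fraction `rho` of
#' centers drawn from an isotropic Gaussian around a planted hotspot,
#' the rest uniform).
#'
#' @param groups Named list; each element a list with `n_patients` and
#'   `tumors_per_patient` (length-2 integer range, inclusive).
#' @param placement Placement model.
#' @param hotspot_centers_mm n x 3 matrix of hotspot centers (world mm);
#'   must lie inside the parenchyma.
#' @param concentration_mm Gaussian standard deviation around a hotspot (mm).
#' @param mixing_fraction Fraction `rho` in \[0, 1\] of hotspot-drawn centers.
#' @param tumor_radius_meanlog,tumor_radius_sdlog Log-normal tumor radius
#'   parameters (mm); radii are clipped to `tumor_radius_range_mm`.
#' @param tumor_radius_range_mm Allowed radius range (mm).
#' @param edema_multiplier_range Edema outer-radius multiplier range; the
#'   edema mask is the concentric shell between the tumor ball and the
#'   scaled ball.
#' @param seed Master seed for cohort sampling.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = list(
                          EGFR = list(n_patients = 10L,
                                      tumors_per_patient = c(5L, 30L)),
                          ALK = list(n_patients = 10L,
                                     tumors_per_patient = c(5L, 30L)),
                          KRAS = list(n_patients = 10L,
                                      tumors_per_patient = c(5L, 30L))),
                        placement = c("uniform", "junction",
                                      "hotspot_mixture"),
                        hotspot_centers_mm = matrix(c(0, 0, 0), 1L),
                        concentration_mm = 5,
                        mixing_fraction = 1,
                        tumor_radius_meanlog = log(4),
                        tumor_radius_sdlog = 0.35,
                        tumor_radius_range_mm = c(2, 12),
                        edema_multiplier_range = c(1.3, 2.0),
                        seed = 1L) {
  placement <- match.arg(placement)
  if (mixing_fraction < 0 || mixing_fraction > 1)
    lm_abort("mixing_fraction must lie in [0, 1]",
             "lesionmap_error_bad_params")
  if (!is.matrix(hotspot_centers_mm) || ncol(hotspot_centers_mm) != 3L)
    lm_abort("hotspot_centers_mm must be an n x 3 matrix",
             "lesionmap_error_bad_params")
  structure(list(groups = groups, placement = placement,
                 hotspot_centers_mm = hotspot_centers_mm,
                 concentration_mm = concentration_mm,
                 mixing_fraction = mixing_fraction,
                 tumor_radius_meanlog = tumor_radius_meanlog,
                 tumor_radius_sdlog = tumor_radius_sdlog,
                 tumor_radius_range_mm = tumor_radius_range_mm,
                 edema_multiplier_range = edema_multiplier_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

ball_voxels <- function(center_ijk, radius_mm, d, spacing) {
  off <- structuring_offsets(radius_mm, spacing, "ball")
  pts <- off + matrix(as.integer(center_ijk), nrow(off), 3L, byrow = TRUE)
  keep <- pts[, 1] >= 0L & pts[, 2] >= 0L & pts[, 3] >= 0L &
    pts[, 1] < d[1] & pts[, 2] < d[2] & pts[, 3] < d[3]
  pts <- pts[keep, , drop = FALSE]
  as.integer(ijk_to_linear(pts, d))
}

draw_center <- function(spec, phantom, mask_idx, d, max_retries = 1000L) {
  if (spec$placement == "uniform") {
    lin <- mask_idx[sample.int(length(mask_idx), 1L)]
    return(list(ijk = as.integer(linear_to_ijk(lin, d)), hotspot = FALSE))
  }
  if (spec$placement == "junction") {
    jv <- phantom$junction_voxels
    lin <- jv[sample.int(length(jv), 1L)]
    return(list(ijk = as.integer(linear_to_ijk(lin, d)), hotspot = FALSE))
  }
  # hotspot_mixture
  if (stats::runif(1) < spec$mixing_fraction) {
    h <- spec$hotspot_centers_mm[
      sample.int(nrow(spec$hotspot_centers_mm), 1L), ]
    for (r in seq_len(max_retries)) {
      w <- stats::rnorm(3L, h, spec$concentration_mm)
      v <- world_to_voxel(phantom$parenchyma, w)
      if (all(v >= 0L) && all(v < d) &&
          phantom$parenchyma$values[v[1] + 1L, v[2] + 1L, v[3] + 1L] == 1)
        return(list(ijk = v, hotspot = TRUE))
    }
  }
  lin <- mask_idx[sample.int(length(mask_idx), 1L)]
  list(ijk = as.integer(linear_to_ijk(lin, d)), hotspot = FALSE)
}

#' Sample a synthetic lesion cohort
#'
#' Draws lesions as digital balls placed at centers from the configured
#' placement model (truncated to the parenchyma), with concentric edema
#' shells, grouped by patient and mutation group. Ground truth (true center,
#' radius, depth against the true pre-closing parenchymal mask, GMD at the
#' center, hotspot origin) is recorded per lesion.
#'
#' @param spec A [cohort_spec()].
#' @param phantom Output of [make_phantom()].
#' @return List with `records` (list of [lesion_record()]s) and
#'   `ground_truth` (data.frame).
#' @export
sample_cohort <- function(spec, phantom) {
  set.seed(spec$seed)
  par_mask <- phantom$parenchyma
  d <- dim(par_mask$values)
  spacing <- voxel_spacing(par_mask)
  mask_idx <- mask_voxel_indices(par_mask)
  pdt <- distance_transform(par_mask)

  if (spec$placement == "hotspot_mixture") {
    for (i in seq_len(nrow(spec$hotspot_centers_mm))) {
      v <- world_to_voxel(par_mask, spec$hotspot_centers_mm[i, ])
      if (any(v < 0L) || any(v >= d) ||
          par_mask$values[v[1] + 1L, v[2] + 1L, v[3] + 1L] != 1)
        lm_abort("hotspot center lies outside the parenchyma",
                 "lesionmap_error_bad_params")
    }
  }

  records <- list()
  gt <- list()
  lesion_n <- 0L
  for (grp in names(spec$groups)) {
    gs <- spec$groups[[grp]]
    for (p in seq_len(gs$n_patients)) {
      pid <- sprintf("%s_p%02d", grp, p)
      rng <- gs$tumors_per_patient
      n_tum <- if (rng[1] == rng[2]) rng[1] else
        sample(seq(rng[1], rng[2]), 1L)
      for (t in seq_len(n_tum)) {
        lesion_n <- lesion_n + 1L
        lid <- sprintf("les%05d", lesion_n)
        ctr <- draw_center(spec, phantom, mask_idx, d)
        radius <- min(max(
          stats::rlnorm(1, spec$tumor_radius_meanlog,
                        spec$tumor_radius_sdlog),
          spec$tumor_radius_range_mm[1]), spec$tumor_radius_range_mm[2])
        tvox <- ball_voxels(ctr$ijk, radius, d, spacing)
        mult <- stats::runif(1, spec$edema_multiplier_range[1],
                             spec$edema_multiplier_range[2])
        evox <- setdiff(ball_voxels(ctr$ijk, radius * mult, d, spacing), tvox)
        records[[lesion_n]] <- lesion_record(
          lid, pid, grp, tvox,
          edema_mask = if (length(evox)) evox else NULL, grid = par_mask)
        gt[[lesion_n]] <- data.frame(
          lesion_id = lid, patient_id = pid, group = grp,
          center_i = ctr$ijk[1], center_j = ctr$ijk[2],
          center_k = ctr$ijk[3],
          radius_mm = radius,
          depth_mm = pdt$values[ctr$ijk[1] + 1L, ctr$ijk[2] + 1L,
                                ctr$ijk[3] + 1L],
          gmd = phantom$gm$values[ctr$ijk[1] + 1L, ctr$ijk[2] + 1L,
                                  ctr$ijk[3] + 1L],
          is_hotspot = ctr$hotspot)
      }
    }
  }
  list(records = records, ground_truth = do.call(rbind, gt))
}

#' Write a synthetic cohort to disk
#'
#' Emits the on-disk layout the pipeline consumes: `cohort.csv` (lesion_id,
#' patient_id, group, tumor_mask_path, edema_mask_path), per-lesion NIfTI
#' masks under `masks/`, the phantom tissue maps, and `ground_truth.csv`.
#'
#' @param cohort Output of [sample_cohort()].
#' @param phantom Output of [make_phantom()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path to `cohort.csv`.
#' @export
cohort_to_disk <- function(cohort, phantom, dir) {
  ids <- vapply(cohort$records, `[[`, "", "lesion_id")
  if (anyDuplicated(ids))
    lm_abort("duplicate lesion_id values; mask files would overwrite each other",
             "lesionmap_error_bad_params")
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$gm, file.path(dir, "gm.nii.gz"))
  write_volume(phantom$wm, file.path(dir, "wm.nii.gz"))
  write_volume(phantom$csf, file.path(dir, "csf.nii.gz"))
  write_volume(phantom$parenchyma, file.path(dir, "parenchyma_true.nii.gz"))
  rows <- lapply(cohort$records, function(rec) {
    tpath <- file.path("masks", sprintf("%s_tumor.nii.gz", rec$lesion_id))
    write_volume(lesion_mask(rec, "tumor"), file.path(dir, tpath))
    epath <- NA_character_
    if (!is.null(rec$edema_voxels)) {
      epath <- file.path("masks", sprintf("%s_edema.nii.gz", rec$lesion_id))
      write_volume(lesion_mask(rec, "edema"), file.path(dir, epath))
    }
    data.frame(lesion_id = rec$lesion_id, patient_id = rec$patient_id,
               group = rec$group, tumor_mask_path = tpath,
               edema_mask_path = epath)
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(file.path(dir, "cohort.csv"))
}

#' Read a cohort from disk
#'
#' Loads a `cohort.csv` (columns lesion_id, patient_id, group,
#' tumor_mask_path, optional edema_mask_path; paths relative to the CSV) and
#' the referenced NIfTI masks into lesion records on a common grid.
#'
#' @param path Path to `cohort.csv`.
#' @return List of [lesion_record()]s.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    lm_abort(sprintf("file not found: %s", path),
             "lesionmap_error_missing_file")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  ref <- NULL
  lapply(seq_len(nrow(tab)), function(i) {
    tmask <- read_volume(file.path(base, tab$tumor_mask_path[i]))
    if (is.null(ref)) ref <<- tmask else assert_compatible(list(ref, tmask))
    emask <- NULL
    if ("edema_mask_path" %in% names(tab) &&
        !is.na(tab$edema_mask_path[i]) && nzchar(tab$edema_mask_path[i])) {
      emask <- read_volume(file.path(base, tab$edema_mask_path[i]))
      assert_compatible(list(ref, emask))
    }
    lesion_record(tab$lesion_id[i], tab$patient_id[i], tab$group[i],
                  tmask, edema_mask = emask)
  })
}
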