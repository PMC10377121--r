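#' Euclidean distance transform of a binary mask
#'
#' At every foreground voxel, the exact Euclidean distance (in mm, using the
#' per-axis voxel spacing from the affine) from the voxel center to the
#' nearest background voxel center; 0 at background voxels. This is the
#' distance transform of the complementary image: a foreground voxel on the
#' outermost layer has value one voxel spacing, not zero.
#'
#' @param mask Binary `volume_grid` with at least one background voxel.
#' @return A `volume_grid` of distances (mm).
#' @export
distance_transform <- function(mask) {
  assert_binary(mask)
  if (all(mask$values == 1))
    lm_abort("mask has no background voxel; distance undefined",
             "lesionmap_error_all_foreground")
  d <- cpp_edt(as.integer(mask$values == 0), dim(mask$values),
               voxel_spacing(mask))
  volume_grid(array(d, dim(mask$values)), mask$affine)
}

linear_to_ijk <- function(lin0, d) {
  cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2], lin0 %/% (d[1] * d[2]))
}

ijk_to_linear <- function(ijk, d) {
  ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3])
}

#' Locate the tumor center
#'
#' The tumor center is the foreground voxel deepest inside the mask: the voxel
#' with the largest distance-transform value of the complementary image. Ties
#' are broken deterministically by the lexicographically smallest (i, j, k).
#'
#' @param tumor_mask Nonempty binary `volume_grid`.
#' @return Integer triple, 0-based voxel index.
#' @export
find_tumor_center <- function(tumor_mask) {
  assert_binary(tumor_mask)
  if (all(tumor_mask$values == 0))
    lm_abort("empty tumor mask", "lesionmap_error_empty_mask")
  dt <- distance_transform(tumor_mask)
  fg <- which(tumor_mask$values == 1)
  vals <- dt$values[fg]
  best <- fg[vals >= max(vals) - 1e-12] - 1L
  ijk <- linear_to_ijk(best, dim(tumor_mask$values))
  ijk[order(ijk[, 1], ijk[, 2], ijk[, 3])[1L], ]
}

#' Tumor depth below the brain surface
#'
#' The depth of a lesion is the value of the parenchymal distance transform at
#' the lesion's center voxel. Centers falling outside the parenchymal mask
#' (registration slack, dural lesions) get depth 0 with a warning.
#'
#' @param center_index 0-based integer triple.
#' @param parenchyma_dt Distance transform of the parenchymal mask, from
#'   [distance_transform()].
#' @return Depth in mm.
#' @export
compute_depth <- function(center_index, parenchyma_dt) {
  center_index <- check_index_range(parenchyma_dt, center_index)
  depth <- parenchyma_dt$values[center_index[1] + 1L, center_index[2] + 1L,
                                center_index[3] + 1L]
  if (depth == 0) {
    warning("tumor center lies outside the parenchymal mask; depth set to 0")
  }
  depth
}

#' Gray matter density at the tumor center
#'
#' Nearest-voxel lookup of the gray-matter probability at the center index
#' (no interpolation: centers are voxel indices by construction).
#'
#' @param center_index 0-based integer triple.
#' @param gm_map Gray-matter probability map (`volume_grid`, values in
#'   \[0, 1\]).
#' @return Probability in \[0, 1\].
#' @export
gmd_at_center <- function(center_index, gm_map) {
  assert_probability(gm_map, "gm map")
  center_index <- check_index_range(gm_map, center_index)
  gm_map$values[center_index[1] + 1L, center_index[2] + 1L,
                center_index[3] + 1L]
}

#' Lesion volumes and edema/tumor ratio
#'
#' Volumes are foreground voxel counts times the physical voxel volume,
#' reported in cm^3. The ratio defaults to edema volume divided by tumor
#' volume; set `ratio_includes_tumor = TRUE` for (edema+tumor)/tumor.
#'
#' @param record A lesion record from [lesion_record()].
#' @param ratio_includes_tumor Include the tumor volume in the numerator.
#' @return List with `tumor_volume_cm3` and, when an edema mask is present,
#'   `edema_volume_cm3` and `edema_tumor_ratio`.
#' @export
lesion_volumes <- function(record, ratio_includes_tumor = FALSE) {
  tmask <- lesion_mask(record, "tumor")
  n_t <- sum(tmask$values)
  if (n_t == 0)
    lm_abort("empty tumor mask", "lesionmap_error_empty_mask")
  vv <- voxel_volume_mm3(tmask)
  out <- list(tumor_volume_cm3 = n_t * vv / 1000)
  if (!is.null(record$edema_voxels)) {
    emask <- lesion_mask(record, "edema")
    n_e <- sum(emask$values)
    out$edema_volume_cm3 <- n_e * vv / 1000
    num <- if (ratio_includes_tumor) n_e + n_t else n_e
    out$edema_tumor_ratio <- num / n_t
  }
  out
}

#' Histogram of gray matter density at tumor centers
#'
#' Histogram of GMD values over \[0, 1\] with `n_bins` equal bins, left-closed
#' and right-open except the last. The peak is the center of the modal bin;
#' ties go to the lower bin.
#'
#' @param gmd Numeric vector of GMD values in \[0, 1\] (e.g. the
#'   `gmd_at_center` column of [compute_lesion_metrics()]).
#' @param n_bins Number of bins (>= 2), default 10.
#' @return List with `breaks`, `counts`, `peak_bin` (1-based), and
#'   `peak_bin_center`.
#' @export
gmd_distribution <- function(gmd, n_bins = 10L) {
  if (length(gmd) == 0L)
    lm_abort("empty GMD vector", "lesionmap_error_empty_input")
  if (n_bins < 2L)
    lm_abort("n_bins must be >= 2", "lesionmap_error_bad_params")
  if (any(gmd < 0 | gmd > 1))
    lm_abort("GMD values must lie in [0, 1]", "lesionmap_error_not_probability")
  bin <- pmin(floor(gmd * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  peak <- which.max(counts) # which.max takes the first (lower) modal bin
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  list(breaks = breaks, counts = counts, peak_bin = peak,
       peak_bin_center = (breaks[peak] + breaks[peak + 1L]) / 2)
}

#' Create a lesion record
#'
#' One metastasis: identifiers, group label, and its masks. Masks are stored
#' sparsely as 0-based linear voxel indices against a reference grid, so large
#' cohorts stay small in memory; [lesion_mask()] materializes a dense binary
#' `volume_grid` on demand.
#'
#' @param lesion_id,patient_id,group Identifiers; `group` is the mutation
#'   group label (e.g. "EGFR", "ALK", "KRAS").
#' @param tumor_mask Binary `volume_grid`, or a vector of 0-based linear voxel
#'   indices (requires `grid`).
#' @param edema_mask Optional, same forms as `tumor_mask`.
#' @param grid Reference `volume_grid` (required when masks are index
#'   vectors).
#' @return A list of class `lesion_record`.
#' @export
lesion_record <- function(lesion_id, patient_id, group, tumor_mask,
                          edema_mask = NULL, grid = NULL) {
  as_voxels <- function(m) {
    if (inherits(m, "volume_grid")) {
      assert_binary(m)
      if (is.null(grid)) grid <<- volume_grid(array(0, dim(m$values)), m$affine)
      which(m$values == 1) - 1L
    } else {
      as.integer(m)
    }
  }
  tv <- as_voxels(tumor_mask)
  if (length(tv) == 0L)
    lm_abort("empty tumor mask", "lesionmap_error_empty_mask")
  ev <- if (is.null(edema_mask)) NULL else as_voxels(edema_mask)
  if (is.null(grid))
    lm_abort("a reference grid is required with index-vector masks",
             "lesionmap_error_bad_params")
  structure(list(lesion_id = as.character(lesion_id),
                 patient_id = as.character(patient_id),
                 group = as.character(group),
                 tumor_voxels = tv, edema_voxels = ev,
                 dim = dim(grid$values), affine = grid$affine),
            class = "lesion_record")
}

#' @rdname lesion_record
#' @param record A `lesion_record`.
#' @param which_mask `"tumor"` or `"edema"`.
#' @export
lesion_mask <- function(record, which_mask = c("tumor", "edema")) {
  which_mask <- match.arg(which_mask)
  vox <- if (which_mask == "tumor") record$tumor_voxels else record$edema_voxels
  if (is.null(vox))
    lm_abort(sprintf("record %s has no %s mask", record$lesion_id, which_mask),
             "lesionmap_error_empty_mask")
  vals <- array(0, record$dim)
  vals[vox + 1L] <- 1
  volume_grid(vals, record$affine)
}

#' Per-lesion metrics table
#'
#' Computes, for every lesion record: the center voxel (deepest point of the
#' tumor mask), its world coordinate, the depth below the parenchymal surface,
#' the gray-matter density at the center, and tumor/edema volumes with their
#' ratio.
#'
#' @param records List of `lesion_record`s.
#' @param parenchyma Binary parenchymal mask (`volume_grid`).
#' @param gm_map Gray-matter probability map (`volume_grid`).
#' @param ratio_includes_tumor Passed to [lesion_volumes()].
#' @return A data.frame, one row per lesion, with columns lesion_id,
#'   patient_id, group, center_i/j/k (0-based), center_x/y/z_mm, depth_mm,
#'   gmd_at_center, tumor_volume_cm3, edema_volume_cm3, edema_tumor_ratio.
#' @export
compute_lesion_metrics <- function(records, parenchyma, gm_map,
                                   ratio_includes_tumor = FALSE) {
  assert_compatible(list(parenchyma, gm_map))
  pdt <- distance_transform(parenchyma)
  rows <- lapply(records, function(rec) {
    tmask <- lesion_mask(rec, "tumor")
    ctr <- find_tumor_center(tmask)
    w <- voxel_to_world(tmask, ctr)
    depth <- suppressWarnings(compute_depth(ctr, pdt))
    vols <- lesion_volumes(rec, ratio_includes_tumor)
    data.frame(lesion_id = rec$lesion_id, patient_id = rec$patient_id,
               group = rec$group,
               center_i = ctr[1], center_j = ctr[2], center_k = ctr[3],
               center_x_mm = w[1], center_y_mm = w[2], center_z_mm = w[3],
               depth_mm = depth,
               gmd_at_center = gmd_at_center(ctr, gm_map),
               tumor_volume_cm3 = vols$tumor_volume_cm3,
               edema_volume_cm3 = vols$edema_volume_cm3 %||% NA_real_,
               edema_tumor_ratio = vols$edema_tumor_ratio %||% NA_real_)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
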