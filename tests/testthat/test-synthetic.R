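test_phantom <- function(ventricle = NULL, shape = c(48L, 48L, 48L)) {
  make_phantom(phantom_spec(shape = shape, voxel_size_mm = 2,
                            semi_axes_mm = c(40, 44, 36),
                            ventricle = ventricle))
}

test_that("phantom tissue maps are consistent probabilities", {
  ph <- test_phantom()
  for (v in list(ph$gm, ph$wm, ph$csf)) {
    expect_true(all(v$values >= 0 & v$values <= 1))
  }
  tot <- ph$gm$values + ph$wm$values + ph$csf$values
  expect_true(all(tot[ph$parenchyma$values == 1] > 0.1))
  expect_true(all(tot[ph$parenchyma$values == 0] == 0))
  # world origin sits at the grid center (voxel 0 at minus half the extent)
  expect_equal(voxel_to_world(ph$gm, c(0, 0, 0)),
               -(dim(ph$gm$values) - 1) / 2 * 2)
  # deterministic
  ph2 <- test_phantom()
  expect_identical(ph$gm$values, ph2$gm$values)
  expect_identical(ph$junction_voxels, ph2$junction_voxels)
})

test_that("junction band voxels carry exactly the junction GMD", {
  ph <- test_phantom()
  expect_gt(length(ph$junction_voxels), 0)
  expect_true(all(ph$gm$values[ph$junction_voxels + 1] == 0.6))
  expect_true(all(ph$parenchyma$values[ph$junction_voxels + 1] == 1))
})

test_that("the mask pipeline recovers the true parenchyma", {
  ph <- test_phantom()
  rec <- build_parenchyma_mask(ph$gm, ph$wm)
  expect_identical(rec$values, ph$parenchyma$values)
  # with a ventricle cavity, hole filling restores the full ellipsoid
  phv <- test_phantom(ventricle = list(semi_axes_mm = c(12, 18, 10),
                                       offset_mm = c(0, 6, 2)))
  cavity <- sum(phv$gm$values + phv$wm$values == 0 &
                  phv$parenchyma$values == 1)
  expect_gt(cavity, 100)
  recv <- build_parenchyma_mask(phv$gm, phv$wm)
  expect_identical(recv$values, phv$parenchyma$values)
})

test_that("interior lesion centers are recovered exactly from the masks", {
  ph <- test_phantom()
  cs <- cohort_spec(groups = list(EGFR = list(n_patients = 3L,
                                              tumors_per_patient = c(8L,
                                                                     8L))),
                    placement = "hotspot_mixture",
                    hotspot_centers_mm = matrix(c(0, 0, 0), 1),
                    concentration_mm = 6, mixing_fraction = 1,
                    tumor_radius_range_mm = c(2, 5), seed = 9)
  cohort <- sample_cohort(cs, ph)
  for (i in seq_along(cohort$records)) {
    ctr <- find_tumor_center(lesion_mask(cohort$records[[i]], "tumor"))
    expect_identical(ctr, as.integer(unlist(
      cohort$ground_truth[i, c("center_i", "center_j", "center_k")],
      use.names = FALSE)))
  }
  # ground-truth depth/gmd match direct lookups at those centers
  pdt <- distance_transform(ph$parenchyma)
  i1 <- as.integer(cohort$ground_truth[1, c("center_i", "center_j",
                                            "center_k")])
  expect_equal(cohort$ground_truth$depth_mm[1], compute_depth(i1, pdt))
  expect_equal(cohort$ground_truth$gmd[1], gmd_at_center(i1, ph$gm))
})

test_that("uniform placement is uniform over the mask octants", {
  ph <- test_phantom()
  cs <- cohort_spec(groups = list(EGFR = list(n_patients = 10L,
                                              tumors_per_patient = c(40L,
                                                                     40L))),
                    placement = "uniform", seed = 17)
  cohort <- sample_cohort(cs, ph)
  gt <- cohort$ground_truth
  d <- dim(ph$parenchyma$values)
  octant <- function(i, j, k) {
    1 + (i >= d[1] / 2) + 2 * (j >= d[2] / 2) + 4 * (k >= d[3] / 2)
  }
  obs <- tabulate(octant(gt$center_i, gt$center_j, gt$center_k), 8)
  msk <- which(ph$parenchyma$values == 1, arr.ind = TRUE) - 1
  expected_p <- tabulate(octant(msk[, 1], msk[, 2], msk[, 3]), 8) / nrow(msk)
  cs_test <- chisq.test(obs, p = expected_p)
  expect_gt(cs_test$p.value, 0.01)
})

test_that("hotspot placement concentrates centers around the hotspot", {
  ph <- test_phantom()
  cs <- cohort_spec(groups = list(EGFR = list(n_patients = 5L,
                                              tumors_per_patient = c(20L,
                                                                     20L))),
                    placement = "hotspot_mixture",
                    hotspot_centers_mm = matrix(c(10, -8, 4), 1),
                    concentration_mm = 5, mixing_fraction = 1, seed = 23)
  cohort <- sample_cohort(cs, ph)
  gt <- cohort$ground_truth
  expect_true(all(gt$is_hotspot))
  w <- t(apply(gt[, c("center_i", "center_j", "center_k")], 1, function(ix)
    voxel_to_world(ph$parenchyma, ix)))
  dist <- sqrt(rowSums(sweep(w, 2, c(10, -8, 4))^2))
  # 3 sigma of an isotropic 3D Gaussian with sigma = 5 mm
  expect_gt(mean(dist <= 15), 0.9)
  # a hotspot outside the brain is rejected
  cs_bad <- cohort_spec(placement = "hotspot_mixture",
                        hotspot_centers_mm = matrix(c(200, 0, 0), 1))
  expect_error(sample_cohort(cs_bad, ph),
               class = "lesionmap_error_bad_params")
})

test_that("junction placement yields the exact junction GMD and modal bin", {
  ph <- test_phantom()
  cs <- cohort_spec(groups = list(EGFR = list(n_patients = 6L,
                                              tumors_per_patient = c(15L,
                                                                     15L))),
                    placement = "junction", seed = 31)
  cohort <- sample_cohort(cs, ph)
  expect_true(all(cohort$ground_truth$gmd == 0.6))
  h <- gmd_distribution(cohort$ground_truth$gmd)
  expect_equal(h$peak_bin_center, 0.65)
  expect_true(h$breaks[which.max(h$counts)] <= 0.6 + 1e-9 &&
                h$breaks[which.max(h$counts) + 1] > 0.6 + 1e-9)
})

test_that("cohort sampling is deterministic in the seed", {
  ph <- small_phantom()
  cs <- cohort_spec(groups = list(EGFR = list(n_patients = 2L,
                                              tumors_per_patient = c(3L,
                                                                     6L))),
                    seed = 12)
  a <- sample_cohort(cs, ph)
  b <- sample_cohort(cs, ph)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$records[[1]]$tumor_voxels, b$records[[1]]$tumor_voxels)
})

test_that("a cohort round-trips through the on-disk layout", {
  tmp <- withr::local_tempdir()
  ph <- small_phantom()
  cs <- cohort_spec(groups = list(EGFR = list(n_patients = 2L,
                                              tumors_per_patient = c(2L,
                                                                     4L)),
                                  ALK = list(n_patients = 2L,
                                             tumors_per_patient = c(2L,
                                                                    4L))),
                    seed = 3)
  cohort <- sample_cohort(cs, ph)
  csv <- cohort_to_disk(cohort, ph, tmp)
  expect_true(file.exists(csv))
  back <- read_cohort(csv)
  expect_equal(length(back), length(cohort$records))
  for (i in seq_along(back)) {
    expect_identical(sort(back[[i]]$tumor_voxels),
                     sort(cohort$records[[i]]$tumor_voxels))
    expect_identical(back[[i]]$group, cohort$records[[i]]$group)
    expect_identical(back[[i]]$patient_id, cohort$records[[i]]$patient_id)
    if (!is.null(cohort$records[[i]]$edema_voxels))
      expect_identical(sort(back[[i]]$edema_voxels),
                       sort(cohort$records[[i]]$edema_voxels))
  }
  gm_back <- read_volume(file.path(tmp, "gm.nii.gz"))
  expect_equal(gm_back$values, ph$gm$values, tolerance = 1e-6)
  expect_error(read_cohort(file.path(tmp, "missing.csv")),
               class = "lesionmap_error_missing_file")
})
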