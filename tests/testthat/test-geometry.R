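test_that("distance transform matches the brute-force oracle exactly", {
  set.seed(101)
  for (r in 1:50) {
    m <- array(as.numeric(runif(1000) < runif(1, 0.2, 0.6)), c(10, 10, 10))
    if (all(m == 1) || all(m == 0)) next
    sp <- sample(c(1, 1.5, 2), 3, replace = TRUE)
    vol <- volume_grid(m, diag(c(sp, 1)))
    expect_equal(distance_transform(vol)$values, bf_distance_transform(m, sp),
                 tolerance = 1e-12)
  }
})

test_that("distance transform closed forms hold", {
  m <- array(0, c(9, 9, 9))
  m[5, 5, 5] <- 1
  dt <- distance_transform(volume_grid(m))
  expect_equal(dt$values[5, 5, 5], 1)
  expect_equal(sum(dt$values), 1)

  cube <- array(0, c(11, 11, 11))
  cube[4:8, 4:8, 4:8] <- 1
  expect_equal(distance_transform(volume_grid(cube))$values[6, 6, 6], 3)

  expect_error(distance_transform(volume_grid(array(1, c(4, 4, 4)))),
               class = "lesionmap_error_all_foreground")
})

test_that("tumor center is the deepest voxel with lexicographic ties", {
  for (rad in 2:6) {
    d <- rep(2L * rad + 9L, 3)
    ctr <- (d + 1) %/% 2
    ball <- digital_ball(d, ctr, rad)
    expect_identical(find_tumor_center(volume_grid(ball)),
                     as.integer(ctr - 1L))
  }
  m <- array(0, c(11, 11, 11))
  m[6, 6, 6] <- 1
  m[6, 6, 7] <- 1
  expect_identical(find_tumor_center(volume_grid(m)), c(5L, 5L, 5L))
  expect_error(find_tumor_center(volume_grid(array(0, c(4, 4, 4)))),
               class = "lesionmap_error_empty_mask")
})

test_that("center of random blobs attains the brute-force maximum depth", {
  set.seed(202)
  for (r in 1:50) {
    m <- random_blob(c(10L, 10L, 10L), sample(20:80, 1))
    dtv <- bf_distance_transform(m)
    ctr <- find_tumor_center(volume_grid(m))
    expect_equal(dtv[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1],
                 max(dtv), tolerance = 1e-12)
  }
})

test_that("depth in a half-space equals offset-plus-one voxel spacings", {
  d <- c(12L, 12L, 20L)
  half <- array(0, d)
  half[, , 1:10] <- 1 # surface at k-index 9 (0-based)
  pdt <- distance_transform(volume_grid(half))
  # center 7 axial steps in from the surface layer
  expect_equal(compute_depth(c(5, 5, 2), pdt), 8)
  # outermost layer
  expect_equal(compute_depth(c(5, 5, 9), pdt), 1)
  # outside the mask: depth 0 with a warning
  expect_warning(d0 <- compute_depth(c(5, 5, 15), pdt))
  expect_equal(d0, 0)
  # monotone: one voxel deeper adds exactly one spacing
  depths <- vapply(0:9, function(k)
    compute_depth(c(5, 5, k), pdt), 0)
  expect_equal(depths, 10:1)
})

test_that("GMD lookup is a nearest-voxel read", {
  g <- volume_grid(array(0.6, c(8, 8, 8)))
  expect_equal(gmd_at_center(c(3, 3, 3), g), 0.6)
  z <- volume_grid(array(0, c(8, 8, 8)))
  expect_equal(gmd_at_center(c(0, 0, 0), z), 0)
  expect_error(gmd_at_center(c(8, 0, 0), g),
               class = "lesionmap_error_index_out_of_range")
})

test_that("volumes scale with the affine", {
  d <- c(20L, 20L, 20L)
  vox <- sample(prod(d), 1000L) - 1L
  grid1 <- volume_grid(array(0, d))
  rec1 <- lesion_record("l1", "p1", "EGFR", vox, grid = grid1)
  expect_equal(lesion_volumes(rec1)$tumor_volume_cm3, 1)
  grid2 <- volume_grid(array(0, d), diag(c(2, 2, 2, 1)))
  rec2 <- lesion_record("l1", "p1", "EGFR", vox, grid = grid2)
  expect_equal(lesion_volumes(rec2)$tumor_volume_cm3, 8)

  rec3 <- lesion_record("l1", "p1", "EGFR", vox[1:500],
                        edema_mask = vox[501:1000] , grid = grid1)
  # ratio = edema voxels / tumor voxels
  v3 <- lesion_volumes(rec3)
  expect_equal(v3$edema_tumor_ratio, 1)
  rec4 <- lesion_record("l1", "p1", "EGFR", vox[1:250],
                        edema_mask = vox[251:1000], grid = grid1)
  expect_equal(lesion_volumes(rec4)$edema_tumor_ratio, 3)
  expect_equal(lesion_volumes(rec4, ratio_includes_tumor = TRUE)$
                 edema_tumor_ratio, 4)
})

test_that("GMD histogram peak follows the modal bin with lower-bin ties", {
  h <- gmd_distribution(rep(0.6, 25), n_bins = 10)
  expect_equal(h$peak_bin_center, 0.65)
  expect_equal(sum(h$counts), 25)
  # ties go to the lower bin
  h2 <- gmd_distribution(c(0.15, 0.15, 0.85, 0.85), n_bins = 10)
  expect_equal(h2$peak_bin_center, 0.15)
  expect_error(gmd_distribution(numeric(0)),
               class = "lesionmap_error_empty_input")
})
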