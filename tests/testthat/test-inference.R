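test_that("null centers are uniform over the mask and reproducible", {
  d <- c(8L, 8L, 8L)
  m <- array(0, d)
  m[4, 4, 4] <- 1
  single <- volume_grid(m)
  set.seed(1)
  ctrs <- simulate_null_centers(5, single, n_sims = 3)
  expect_true(all(ctrs[, 1] == 3 & ctrs[, 2] == 3 & ctrs[, 3] == 3))

  m2 <- array(0, d)
  m2[2, 2, 2] <- 1
  m2[6, 6, 6] <- 1
  two <- volume_grid(m2)
  set.seed(2)
  draws <- simulate_null_centers(1, two, n_sims = 100000)
  frac <- mean(draws[, 1] == 1)
  se <- sqrt(0.25 / 100000)
  expect_lt(abs(frac - 0.5), 3 * se)

  set.seed(7)
  a <- simulate_null_centers(10, two, n_sims = 5)
  set.seed(7)
  b <- simulate_null_centers(10, two, n_sims = 5)
  expect_identical(a, b)
  expect_error(simulate_null_centers(3, volume_grid(array(0, d))),
               class = "lesionmap_error_empty_mask")
})

test_that("patient-block relocation keeps blocks rigid and in-mask", {
  ph <- small_phantom()
  obs <- rbind(c(12L, 12L, 12L), c(12L, 13L, 12L), c(13L, 12L, 12L),
               c(11L, 11L, 11L), c(11L, 11L, 12L))
  set.seed(31)
  ctrs <- simulate_null_centers(5, ph$parenchyma, n_sims = 20,
                                mode = "patient_block",
                                observed_centers = obs,
                                patient_sizes = c(3, 2))
  d <- dim(ph$parenchyma$values)
  lin <- ctrs[, 1] + d[1] * (ctrs[, 2] + d[2] * ctrs[, 3])
  expect_true(all(ph$parenchyma$values[lin + 1] == 1))
  # within each simulated map, the first block keeps its internal offsets
  for (s in 1:5) {
    blk <- ctrs[(s - 1) * 5 + 1:3, ]
    expect_equal(sweep(blk, 2, blk[1, ]), sweep(obs[1:3, ], 2, obs[1, ]))
  }
})

test_that("voxel thresholds reproduce the dense-storage quantile oracle", {
  ph <- small_phantom(shape = c(12L, 12L, 12L), voxel = 2)
  cfg <- null_config(n_voxel_sims = 400, voxel_p = 0.01, seed = 5)
  thr <- suppressWarnings(
    estimate_voxel_thresholds(3, ph$parenchyma, 6, cfg))
  # rebuild the same simulated maps densely and take quantiles per voxel
  seeds <- lesionmap:::phase_seeds(cfg$seed)
  set.seed(seeds[1])
  ctrs <- simulate_null_centers(3, ph$parenchyma, n_sims = 400)
  d <- dim(ph$parenchyma$values)
  dense <- array(0, c(prod(d), 400))
  for (s in 1:400) {
    fm <- build_frequency_map(ctrs[(s - 1) * 3 + 1:3, , drop = FALSE], 6,
                              ph$parenchyma)
    dense[, s] <- as.numeric(fm$grid$values)
  }
  oracle <- apply(dense, 1, quantile, probs = 0.99, type = 5, names = FALSE)
  expect_equal(as.numeric(thr$grid$values), oracle, tolerance = 1e-12)
  # a voxel farther than the radius from every mask voxel has threshold 0
  expect_equal(thr$grid$values[1, 1, 1], 0)
})

test_that("degenerate single-voxel null gives threshold 1 inside the sphere", {
  d <- c(7L, 7L, 7L)
  m <- array(0, d)
  m[4, 4, 4] <- 1
  single <- volume_grid(m)
  cfg <- null_config(n_voxel_sims = 50, voxel_p = 0.1, seed = 3)
  thr <- suppressWarnings(estimate_voxel_thresholds(1, single, 1, cfg))
  expect_equal(thr$grid$values[4, 4, 4], 1)
  expect_equal(thr$grid$values[4, 4, 5], 1)
  expect_equal(thr$grid$values[1, 1, 1], 0)
})

test_that("quantile resolution warning fires when sims are too few", {
  ph <- small_phantom(shape = c(12L, 12L, 12L))
  cfg <- null_config(n_voxel_sims = 100, voxel_p = 0.001, seed = 1)
  expect_warning(estimate_voxel_thresholds(2, ph$parenchyma, 6, cfg),
                 "resolves")
})

test_that("cluster-size threshold follows the expected-count rule", {
  sizes <- c(rep(1L, 99000L), rep(3L, 1000L))
  expect_equal(cluster_size_threshold(sizes, 100000, 0.05), 1L)
  # no suprathreshold voxel ever -> threshold 0, empty multiset
  expect_equal(cluster_size_threshold(integer(0), 1000, 0.05), 0L)
  # monotone: raising cluster_p never increases T
  set.seed(4)
  szs <- sample(1:50, 5000, replace = TRUE)
  ts <- vapply(c(0.01, 0.05, 0.1, 0.5),
               function(p) cluster_size_threshold(szs, 1000, p), 0L)
  expect_true(all(diff(ts) <= 0))
  # max_cluster rule uses per-map maxima
  mm <- c(rep(0L, 90), rep(10L, 10))
  expect_equal(cluster_size_threshold(integer(0), 100, 0.05, "max_cluster",
                                      map_max = mm), 10L)
})

test_that("cluster p-values use the add-one rank estimator", {
  cn <- structure(list(calibration_rule = "expected_count",
                       null_sizes = c(5L, 8L, 12L), n_sims = 9999L),
                  class = "cluster_null")
  expect_equal(cluster_p_value(100, cn), 1e-4)
  expect_equal(cluster_p_value(8, cn), 3 / 10000)
  expect_equal(cluster_p_value(1, cn), 4 / 10000)
})

test_that("calibration is deterministic and provenance-checked", {
  ph <- small_phantom()
  cfg <- null_config(n_voxel_sims = 150, n_cluster_sims = 200,
                     voxel_p = 0.01, seed = 11)
  thr1 <- suppressWarnings(
    estimate_voxel_thresholds(10, ph$parenchyma, 12, cfg))
  thr2 <- suppressWarnings(
    estimate_voxel_thresholds(10, ph$parenchyma, 12, cfg))
  expect_identical(thr1$grid$values, thr2$grid$values)
  cn1 <- calibrate_cluster_threshold(10, ph$parenchyma, 12, thr1, cfg)
  cn2 <- calibrate_cluster_threshold(10, ph$parenchyma, 12, thr2, cfg)
  expect_identical(cn1$null_sizes, cn2$null_sizes)
  expect_identical(cn1$cluster_size_threshold, cn2$cluster_size_threshold)
  # wrong n_centers is a provenance error
  expect_error(calibrate_cluster_threshold(11, ph$parenchyma, 12, thr1, cfg),
               class = "lesionmap_error_provenance")
  # wrong radius too
  expect_error(calibrate_cluster_threshold(10, ph$parenchyma, 10, thr1, cfg),
               class = "lesionmap_error_provenance")
})

test_that("observed maps against their own null rarely yield clusters", {
  ph <- small_phantom()
  cfg <- null_config(n_voxel_sims = 300, n_cluster_sims = 400,
                     voxel_p = 0.005, cluster_p = 0.05, seed = 21)
  n_cent <- 20L
  thr <- suppressWarnings(
    estimate_voxel_thresholds(n_cent, ph$parenchyma, 12, cfg))
  cn <- calibrate_cluster_threshold(n_cent, ph$parenchyma, 12, thr, cfg)
  set.seed(909)
  hits <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    ctrs <- simulate_null_centers(n_cent, ph$parenchyma)
    fm <- build_frequency_map(ctrs, 12, ph$parenchyma)
    cl <- find_significant_clusters(fm, thr, cn, ph$parenchyma)
    if (length(cl) > 0L) hits <- hits + 1L
    }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(hits / n_rep, 0.05 + 3 * se)
})

test_that("a planted hotspot is recovered as a significant cluster", {
  ph <- small_phantom()
  cs <- cohort_spec(groups = list(EGFR = list(n_patients = 6L,
                                              tumors_per_patient = c(10L,
                                                                     10L))),
                    placement = "hotspot_mixture",
                    hotspot_centers_mm = matrix(c(0, 0, 0), 1),
                    concentration_mm = 5, mixing_fraction = 1, seed = 5)
  cohort <- sample_cohort(cs, ph)
  metrics <- compute_lesion_metrics(cohort$records, ph$parenchyma, ph$gm)
  ctrs <- as.matrix(metrics[, c("center_i", "center_j", "center_k")])
  cfg <- null_config(n_voxel_sims = 300, n_cluster_sims = 400,
                     voxel_p = 0.005, seed = 13)
  thr <- suppressWarnings(
    estimate_voxel_thresholds(nrow(ctrs), ph$parenchyma, 12, cfg))
  cn <- calibrate_cluster_threshold(nrow(ctrs), ph$parenchyma, 12, thr, cfg)
  fm <- build_frequency_map(ctrs, 12, ph$parenchyma, group = "EGFR")
  cl <- find_significant_clusters(fm, thr, cn, ph$parenchyma)
  expect_gte(length(cl), 1L)
  hot_vox <- world_to_voxel(ph$parenchyma, c(0, 0, 0))
  contains <- vapply(cl, function(x)
    any(x$member_voxels[, 1] == hot_vox[1] &
          x$member_voxels[, 2] == hot_vox[2] &
          x$member_voxels[, 3] == hot_vox[3]), TRUE)
  expect_true(any(contains))
  expect_lt(cl[[1]]$p_value, 0.05)
  rep_tab <- cluster_report(cl, "EGFR")
  expect_equal(nrow(rep_tab), length(cl))
  expect_true(all(c("size_voxels", "p_value") %in% names(rep_tab)))
})
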