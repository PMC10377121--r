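#' Null-model configuration
#'
#' Settings for the uniform-random null calibration: numbers of simulated
#' null frequency maps for the voxel-threshold and cluster-threshold phases,
#' the voxel-wise and cluster-wise levels, cluster connectivity, the master
#' seed, and the cluster calibration rule. Defaults mirror the full-scale
#' analysis (10,000 voxel simulations at p = 0.001; 1,000,000 cluster
#' simulations at p = 0.05); scale the counts down for exploratory runs.
#'
#' @param n_voxel_sims Null maps for per-voxel quantile thresholds.
#' @param n_cluster_sims Null maps for the cluster-size threshold.
#' @param voxel_p Voxel-wise level in (0, 1).
#' @param cluster_p Cluster-wise level in (0, 1).
#' @param connectivity Cluster connectivity: 6, 18 or 26 (default 26).
#' @param seed Master seed; the voxel and cluster phases draw from two
#'   independent streams derived from it.
#' @param calibration_rule `"expected_count"` (default; bounds the expected
#'   number of oversize clusters per map, i.e. "5 in every 100 images") or
#'   `"max_cluster"` (bounds the rate of maps whose largest cluster is
#'   oversize, FWER-style).
#' @param quantile_type `"linear"` (interpolated order statistics, the
#'   Matlab quantile convention) or `"ceiling"` (conservative upper rank).
#' @return A list of class `null_config`.
#' @export
null_config <- function(n_voxel_sims = 10000L, n_cluster_sims = 1000000L,
                        voxel_p = 0.001, cluster_p = 0.05,
                        connectivity = 26L, seed = 1L,
                        calibration_rule = c("expected_count", "max_cluster"),
                        quantile_type = c("linear", "ceiling")) {
  calibration_rule <- match.arg(calibration_rule)
  quantile_type <- match.arg(quantile_type)
  if (!(voxel_p > 0 && voxel_p < 1) || !(cluster_p > 0 && cluster_p < 1))
    lm_abort("voxel_p and cluster_p must lie strictly in (0, 1)",
             "lesionmap_error_bad_params")
  if (n_voxel_sims < 1L || n_cluster_sims < 1L)
    lm_abort("simulation counts must be >= 1", "lesionmap_error_bad_params")
  if (!connectivity %in% c(6L, 18L, 26L))
    lm_abort("connectivity must be 6, 18 or 26", "lesionmap_error_bad_params")
  structure(list(n_voxel_sims = as.integer(n_voxel_sims),
                 n_cluster_sims = as.integer(n_cluster_sims),
                 voxel_p = voxel_p, cluster_p = cluster_p,
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed),
                 calibration_rule = calibration_rule,
                 quantile_type = quantile_type),
            class = "null_config")
}

# Independent per-phase seeds derived from the master seed; reusing draws
# between the threshold and cluster phases would bias the calibration.
phase_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, 3L)
}

mask_voxel_indices <- function(parenchyma) {
  assert_binary(parenchyma, "parenchymal mask")
  idx <- which(parenchyma$values == 1) - 1L
  if (length(idx) == 0L)
    lm_abort("empty parenchymal mask", "lesionmap_error_empty_mask")
  idx
}

#' Simulate uniformly random null tumor centers
#'
#' Draws `n_sims` sets of `n_centers` centers, each drawn independently and
#' uniformly (with replacement) over the foreground voxels of the parenchymal
#' mask; this relocates every tumor center to a random in-mask position. In
#' `"patient_block"` mode, centers are grouped by `patient_sizes` and each
#' patient's set is relocated rigidly by one common random translation
#' (with in-mask rejection and bounded retries, falling back to independent
#' draws for that patient).
#'
#' Uses R's current RNG stream; call `set.seed()` beforehand for
#' reproducibility (the higher-level calibration functions do this from
#' their `null_config` seed).
#'
#' @param n_centers Centers per simulated map (the observed group's tumor
#'   count).
#' @param parenchyma Binary parenchymal mask.
#' @param n_sims Number of simulated center sets (default 1).
#' @param mode `"independent"` (default) or `"patient_block"`.
#' @param observed_centers,patient_sizes For `"patient_block"`: the observed
#'   n x 3 center matrix and the tumor count per patient (sums to
#'   `n_centers`).
#' @param max_retries Per-patient rejection retries in block mode.
#' @return An (`n_sims` * `n_centers`) x 3 integer matrix of 0-based voxel
#'   indices, simulations stacked in order.
#' @export
simulate_null_centers <- function(n_centers, parenchyma, n_sims = 1L,
                                  mode = c("independent", "patient_block"),
                                  observed_centers = NULL,
                                  patient_sizes = NULL,
                                  max_retries = 100L) {
  mode <- match.arg(mode)
  if (n_centers < 1L)
    lm_abort("n_centers must be >= 1", "lesionmap_error_bad_params")
  idx <- mask_voxel_indices(parenchyma)
  d <- dim(parenchyma$values)
  if (mode == "independent") {
    draws <- idx[sample.int(length(idx), n_sims * n_centers, replace = TRUE)]
    out <- linear_to_ijk(draws, d)
  } else {
    if (is.null(observed_centers) || is.null(patient_sizes) ||
        sum(patient_sizes) != n_centers)
      lm_abort("patient_block mode needs observed_centers and patient_sizes summing to n_centers",
               "lesionmap_error_bad_params")
    inmask <- array(FALSE, d)
    inmask[idx + 1L] <- TRUE
    blocks <- split(seq_len(n_centers),
                    rep(seq_along(patient_sizes), patient_sizes))
    out <- matrix(0L, n_sims * n_centers, 3L)
    for (s in seq_len(n_sims)) {
      for (b in seq_along(blocks)) {
        rows <- blocks[[b]]
        obs <- observed_centers[rows, , drop = FALSE]
        placed <- NULL
        for (r in seq_len(max_retries)) {
          anchor <- linear_to_ijk(idx[sample.int(length(idx), 1L)], d)
          shift <- matrix(anchor - obs[1L, ], nrow(obs), 3L, byrow = TRUE)
          cand <- obs + shift
          ok <- all(cand >= 0L) &&
            all(cand < matrix(d, nrow(cand), 3L, byrow = TRUE)) &&
            all(inmask[cand + 1L])
          if (ok) { placed <- cand; break }
        }
        if (is.null(placed))
          placed <- linear_to_ijk(
            idx[sample.int(length(idx), nrow(obs), replace = TRUE)], d)
        out[(s - 1L) * n_centers + rows, ] <- placed
      }
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Fit per-voxel thresholds from the uniform null
#'
#' Simulates `n_voxel_sims` null frequency maps (uniform random centers,
#' sphere kernel) and takes, at every voxel, the empirical 1 - `voxel_p`
#' quantile of its null values. Only per-voxel count histograms are kept in
#' memory; the simulated maps are never stored.
#'
#' @param n_centers Tumor count of the observed group.
#' @param parenchyma Binary parenchymal mask.
#' @param radius_mm Sphere radius in mm.
#' @param config A [null_config()].
#' @return A `voxel_threshold_map`: list with `grid` (thresholds on the
#'   frequency scale), `voxel_p`, `n_sims`, `n_centers`, `radius_mm`, `seed`,
#'   `quantile_type`, and a mask fingerprint for provenance checks.
#' @export
estimate_voxel_thresholds <- function(n_centers, parenchyma, radius_mm,
                                      config = null_config()) {
  if (config$n_voxel_sims < 1 / config$voxel_p)
    warning(sprintf(
      "n_voxel_sims = %d resolves the 1 - %g quantile poorly (< 1/p sims)",
      config$n_voxel_sims, config$voxel_p))
  seeds <- phase_seeds(config$seed)
  d <- dim(parenchyma$values)
  off <- sphere_offsets(radius_mm, voxel_spacing(parenchyma))
  set.seed(seeds[1L])
  centers <- simulate_null_centers(n_centers, parenchyma,
                                   n_sims = config$n_voxel_sims)
  hist <- cpp_null_count_histogram(d, off, centers, config$n_voxel_sims,
                                   n_centers)
  qtype <- if (config$quantile_type == "linear") 5L else 0L
  thr_counts <- cpp_quantile_from_counts(hist, 1 - config$voxel_p, qtype)
  structure(list(
    grid = volume_grid(array(thr_counts / n_centers, d), parenchyma$affine),
    voxel_p = config$voxel_p, n_sims = config$n_voxel_sims,
    n_centers = as.integer(n_centers), radius_mm = radius_mm,
    seed = config$seed, quantile_type = config$quantile_type,
    mask_fingerprint = grid_fingerprint(parenchyma)
  ), class = "voxel_threshold_map")
}

check_provenance <- function(a_fp, b_fp, a_n, b_n, a_r, b_r, what) {
  if (!isTRUE(all.equal(a_fp, b_fp)) || a_n != b_n ||
      !isTRUE(all.equal(a_r, b_r)))
    lm_abort(sprintf(
      "mismatched provenance between %s (mask, n_centers or radius differ)",
      what), "lesionmap_error_provenance")
  invisible(TRUE)
}

#' Cluster-size threshold from pooled null cluster sizes
#'
#' Under the `"expected_count"` rule, the threshold is the smallest integer T
#' such that the pooled number of null clusters with size > T, divided by the
#' number of simulated maps, is at most `cluster_p` (so oversize clusters
#' occur at most `cluster_p` times per map on average, e.g. 5 in every 100
#' maps at p = 0.05). Under `"max_cluster"`, T is the smallest integer such
#' that at most a `cluster_p` fraction of maps have a largest cluster
#' exceeding T.
#'
#' @param sizes Integer vector of null cluster sizes pooled over maps.
#' @param n_sims Number of simulated maps the sizes came from.
#' @param cluster_p Cluster-wise level.
#' @param rule `"expected_count"` or `"max_cluster"`.
#' @param map_max Per-map maximum cluster sizes (required for
#'   `"max_cluster"`).
#' @return Non-negative integer threshold.
#' @export
cluster_size_threshold <- function(sizes, n_sims, cluster_p,
                                   rule = c("expected_count", "max_cluster"),
                                   map_max = NULL) {
  rule <- match.arg(rule)
  if (rule == "expected_count") {
    if (length(sizes) == 0L) return(0L)
    t_cand <- 0L
    while (sum(sizes > t_cand) / n_sims > cluster_p) t_cand <- t_cand + 1L
    t_cand
  } else {
    if (is.null(map_max))
      lm_abort("max_cluster rule needs per-map maxima",
               "lesionmap_error_bad_params")
    t_cand <- 0L
    while (mean(map_max > t_cand) > cluster_p) t_cand <- t_cand + 1L
    t_cand
  }
}

#' Calibrate the cluster-size threshold from the uniform null
#'
#' Simulates `n_cluster_sims` fresh null frequency maps (an RNG stream
#' independent of the voxel-threshold phase), applies the fitted per-voxel
#' thresholds (strict exceedance, restricted to the parenchymal mask), labels
#' connected components, and records cluster sizes. Only the sizes are
#' retained, never the maps.
#'
#' @inheritParams estimate_voxel_thresholds
#' @param thresholds A `voxel_threshold_map` fitted with the same mask,
#'   `n_centers` and radius.
#' @return A `cluster_null`: list with `cluster_size_threshold`,
#'   `null_sizes` (pooled multiset), `map_max`, `per_map_n_clusters`,
#'   `n_sims`, rule, connectivity, seed, and provenance fields.
#' @export
calibrate_cluster_threshold <- function(n_centers, parenchyma, radius_mm,
                                        thresholds,
                                        config = null_config()) {
  check_provenance(thresholds$mask_fingerprint, grid_fingerprint(parenchyma),
                   thresholds$n_centers, n_centers,
                   thresholds$radius_mm, radius_mm,
                   "voxel thresholds and cluster calibration")
  seeds <- phase_seeds(config$seed)
  d <- dim(parenchyma$values)
  off <- sphere_offsets(radius_mm, voxel_spacing(parenchyma))
  set.seed(seeds[2L])
  stats <- chunked_null_cluster_stats(n_centers, parenchyma, off,
                                      config$n_cluster_sims,
                                      thresholds$grid$values * n_centers,
                                      config$connectivity)
  thr <- cluster_size_threshold(stats$pooled_sizes, config$n_cluster_sims,
                                config$cluster_p, config$calibration_rule,
                                map_max = stats$per_map_max_size)
  structure(list(
    cluster_size_threshold = thr,
    null_sizes = stats$pooled_sizes,
    map_max = stats$per_map_max_size,
    per_map_n_clusters = stats$per_map_n_clusters,
    n_sims = config$n_cluster_sims, cluster_p = config$cluster_p,
    calibration_rule = config$calibration_rule,
    connectivity = config$connectivity, seed = config$seed,
    n_centers = as.integer(n_centers), radius_mm = radius_mm,
    mask_fingerprint = grid_fingerprint(parenchyma)
  ), class = "cluster_null")
}

# Runs the null-map cluster statistics in chunks of simulations so the
# center matrix never grows with the total simulation count. Uniform draws
# with replacement consume the RNG stream sequentially, so chunking is
# bit-identical to a single pass.
chunked_null_cluster_stats <- function(n_centers, parenchyma, offsets,
                                       n_sims, thr_counts, connectivity,
                                       chunk_size = 20000L) {
  d <- dim(parenchyma$values)
  mask_int <- as.integer(parenchyma$values)
  per_map_exceed <- integer(0)
  per_map_nclus <- integer(0)
  per_map_max <- integer(0)
  pooled <- list()
  n_mask <- NA_real_
  done <- 0L
  while (done < n_sims) {
    k <- min(chunk_size, n_sims - done)
    centers <- simulate_null_centers(n_centers, parenchyma, n_sims = k)
    st <- cpp_null_cluster_stats(d, offsets, centers, k, n_centers,
                                 thr_counts, mask_int, connectivity)
    per_map_exceed <- c(per_map_exceed, st$per_map_exceed)
    per_map_nclus <- c(per_map_nclus, st$per_map_n_clusters)
    per_map_max <- c(per_map_max, st$per_map_max_size)
    pooled[[length(pooled) + 1L]] <- st$pooled_sizes
    n_mask <- st$n_mask_voxels
    done <- done + k
  }
  list(per_map_exceed = per_map_exceed,
       per_map_n_clusters = per_map_nclus,
       per_map_max_size = per_map_max,
       pooled_sizes = unlist(pooled),
       n_mask_voxels = n_mask)
}

#' Monte-Carlo cluster p-value
#'
#' Add-one rank estimator against the null cluster-size multiset:
#' (1 + number of null entries >= size) / (1 + number of simulated maps).
#' Never returns 0; a cluster larger than every null entry over N maps gets
#' 1 / (N + 1).
#'
#' @param size Observed cluster size (voxels).
#' @param cluster_null A `cluster_null`.
#' @return p-value in (0, 1].
#' @export
cluster_p_value <- function(size, cluster_null) {
  entries <- if (cluster_null$calibration_rule == "expected_count")
    cluster_null$null_sizes else cluster_null$map_max
  (1 + sum(entries >= size)) / (1 + cluster_null$n_sims)
}

#' Report significant clusters of an observed frequency map
#'
#' Applies the per-voxel thresholds (strict exceedance, within the
#' parenchymal mask), labels connected components, discards components not
#' exceeding the calibrated cluster-size threshold, and attaches a
#' Monte-Carlo p-value to each survivor. The representative coordinate is the
#' world position of the cluster's peak-frequency voxel (ties broken by the
#' lexicographically smallest index).
#'
#' @param observed A `frequency_map` built with the same radius and tumor
#'   count used for calibration.
#' @param thresholds A `voxel_threshold_map`.
#' @param cluster_null A `cluster_null`.
#' @param parenchyma Binary parenchymal mask.
#' @return List of `cluster_record`s (member_voxels as 0-based n x 3 matrix,
#'   size, representative_index, representative_world_mm, peak_frequency,
#'   p_value); also see [cluster_report()].
#' @export
find_significant_clusters <- function(observed, thresholds, cluster_null,
                                      parenchyma) {
  assert_compatible(list(observed$grid, thresholds$grid, parenchyma))
  check_provenance(thresholds$mask_fingerprint, grid_fingerprint(parenchyma),
                   thresholds$n_centers, observed$n_tumors,
                   thresholds$radius_mm, observed$radius_mm,
                   "observed map and voxel thresholds")
  check_provenance(cluster_null$mask_fingerprint,
                   grid_fingerprint(parenchyma),
                   cluster_null$n_centers, observed$n_tumors,
                   cluster_null$radius_mm, observed$radius_mm,
                   "observed map and cluster null")
  if (thresholds$seed != cluster_null$seed)
    lm_abort("mismatched provenance: thresholds and cluster null built from different master seeds",
             "lesionmap_error_provenance")
  d <- dim(observed$grid$values)
  sup <- which(observed$grid$values > thresholds$grid$values &
                 parenchyma$values == 1) - 1L
  if (length(sup) == 0L) return(list())
  labels <- cpp_label_components(d, sup, cluster_null$connectivity)
  out <- list()
  for (lab in seq_len(max(labels))) {
    vox <- sup[labels == lab]
    size <- length(vox)
    if (size <= cluster_null$cluster_size_threshold) next
    ijk <- linear_to_ijk(vox, d)
    freq <- observed$grid$values[vox + 1L]
    peak <- which(freq >= max(freq) - 1e-12)
    peak <- peak[order(ijk[peak, 1], ijk[peak, 2], ijk[peak, 3])[1L]]
    rep_ijk <- ijk[peak, ]
    out[[length(out) + 1L]] <- structure(list(
      member_voxels = ijk, size = size,
      representative_index = rep_ijk,
      representative_world_mm = voxel_to_world(observed$grid, rep_ijk),
      peak_frequency = max(freq),
      p_value = cluster_p_value(size, cluster_null)
    ), class = "cluster_record")
  }
  out[order(vapply(out, `[[`, 0, "p_value"),
            -vapply(out, `[[`, 0L, "size"))]
}

#' Tabulate cluster records
#'
#' Flattens a list of `cluster_record`s into the standard report table
#' (group, cluster_id, size_voxels, representative mm coordinates, p_value).
#' Anatomical labels are deliberately not attached; the coordinates allow
#' external atlas lookup.
#'
#' @param clusters List from [find_significant_clusters()].
#' @param group Group label for the report.
#' @return A data.frame (0 rows when no cluster survives).
#' @export
cluster_report <- function(clusters, group = NA_character_) {
  if (length(clusters) == 0L)
    return(data.frame(group = character(), cluster_id = integer(),
                      size_voxels = integer(), rep_x_mm = numeric(),
                      rep_y_mm = numeric(), rep_z_mm = numeric(),
                      p_value = numeric()))
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(group = group, cluster_id = i, size_voxels = cl$size,
               rep_x_mm = cl$representative_world_mm[1],
               rep_y_mm = cl$representative_world_mm[2],
               rep_z_mm = cl$representative_world_mm[3],
               p_value = cl$p_value)
  }))
}

#' Empirical calibration check on fresh null maps
#'
#' Simulates fresh null maps from a third RNG stream and measures (i) the
#' mean in-mask per-voxel strict-exceedance rate of the fitted thresholds and
#' (ii) when a `cluster_null` is supplied, the fraction of maps containing at
#' least one surviving cluster. Monte-Carlo standard errors are across maps.
#'
#' @inheritParams calibrate_cluster_threshold
#' @param cluster_null Optional `cluster_null`.
#' @param n_sims Number of fresh maps.
#' @param seed Seed for the fresh stream (default derives a third stream from
#'   `config$seed`).
#' @return List with `voxel_rate`, `voxel_rate_se`, and (when applicable)
#'   `cluster_rate`, `cluster_rate_se`, plus the per-map statistics.
#' @export
null_calibration_check <- function(n_centers, parenchyma, radius_mm,
                                   thresholds, cluster_null = NULL,
                                   n_sims = 1000L, config = null_config(),
                                   seed = NULL) {
  check_provenance(thresholds$mask_fingerprint, grid_fingerprint(parenchyma),
                   thresholds$n_centers, n_centers,
                   thresholds$radius_mm, radius_mm,
                   "voxel thresholds and calibration check")
  if (is.null(seed)) seed <- phase_seeds(config$seed)[3L]
  d <- dim(parenchyma$values)
  off <- sphere_offsets(radius_mm, voxel_spacing(parenchyma))
  set.seed(seed)
  stats <- chunked_null_cluster_stats(n_centers, parenchyma, off, n_sims,
                                      thresholds$grid$values * n_centers,
                                      config$connectivity)
  per_map_rate <- stats$per_map_exceed / stats$n_mask_voxels
  out <- list(voxel_rate = mean(per_map_rate),
              voxel_rate_se = sd(per_map_rate) / sqrt(n_sims),
              per_map_exceed = stats$per_map_exceed,
              n_mask_voxels = stats$n_mask_voxels)
  if (!is.null(cluster_null)) {
    surv <- stats$per_map_max_size > cluster_null$cluster_size_threshold
    out$cluster_rate <- mean(surv)
    out$cluster_rate_se <- sd(surv) / sqrt(n_sims)
    out$per_map_max_size <- stats$per_map_max_size
  }
  out
}
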