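# Brute-force reference implementations used as independent oracles, plus
# small fixture builders. All deliberately naive: direct set computations
# over every voxel pair, no shared code with the package internals.

# Distance (mm) from each foreground voxel to the nearest background voxel
# center, by exhaustive minimization.
bf_distance_transform <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  out <- array(0, d)
  bg <- which(mask == 0, arr.ind = TRUE)
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(out)
  for (r in seq_len(nrow(fg))) {
    df <- sweep(bg, 2, fg[r, ]) %*% diag(spacing)
    out[fg[r, 1], fg[r, 2], fg[r, 3]] <- sqrt(min(rowSums(df^2)))
  }
  out
}

# Per-voxel count of centers within radius (mm), by scanning every voxel.
bf_frequency_counts <- function(centers0, radius_mm, d, spacing = c(1, 1, 1)) {
  out <- array(0L, d)
  for (i in 0:(d[1] - 1)) for (j in 0:(d[2] - 1)) for (k in 0:(d[3] - 1)) {
    dx <- (centers0[, 1] - i) * spacing[1]
    dy <- (centers0[, 2] - j) * spacing[2]
    dz <- (centers0[, 3] - k) * spacing[3]
    out[i + 1, j + 1, k + 1] <- sum(dx^2 + dy^2 + dz^2 <= radius_mm^2 + 1e-9)
  }
  out
}

# Random connected blob grown by a lattice random walk from the volume center.
random_blob <- function(d = c(10L, 10L, 10L), n_target = 50L) {
  m <- array(0, d)
  cur <- pmax(1L, d %/% 2L)
  m[cur[1], cur[2], cur[3]] <- 1
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(n_target * 4L)) {
    cand <- cur + steps[sample.int(6L, 1L), ]
    if (any(cand < 1L) || any(cand > d)) next
    cur <- cand
    m[cur[1], cur[2], cur[3]] <- 1
    if (sum(m) >= n_target) break
  }
  m
}

# Digital ball mask of given voxel radius centered at ctr (1-based).
digital_ball <- function(d, ctr, radius_vox) {
  m <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if ((i - ctr[1])^2 + (j - ctr[2])^2 + (k - ctr[3])^2 <= radius_vox^2)
      m[i, j, k] <- 1
  m
}

# Small test phantom shared across inference tests (cheap to rebuild).
small_phantom <- function(shape = c(24L, 24L, 24L), voxel = 2) {
  make_phantom(phantom_spec(shape = shape, voxel_size_mm = voxel,
                            semi_axes_mm = c(0.4, 0.44, 0.36) * shape[1] *
                              voxel,
                            ventricle = NULL))
}
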