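#' Parenchymal mask parameters
#'
#' Parameters for building the brain parenchymal mask from tissue probability
#' maps: the probability threshold applied to the summed gray+white map
#' (default 0.1, inclusive), the radius of the ball (or cube) structuring
#' element used for morphological closing (mm), and an explicit hole fill.
#'
#' @param probability_threshold Threshold on gm+wm, strictly in (0,1).
#' @param closing_radius_mm Structuring-element radius in mm (> 0).
#' @param structuring_element `"ball"` (Euclidean) or `"cube"` (Chebyshev).
#' @param fill_holes Flood-fill fully enclosed cavities (e.g. ventricles)
#'   after closing. The closing alone cannot fill large cavities.
#' @return A list of class `parenchyma_params`.
#' @export
parenchyma_params <- function(probability_threshold = 0.1,
                              closing_radius_mm = 3,
                              structuring_element = c("ball", "cube"),
                              fill_holes = TRUE) {
  structuring_element <- match.arg(structuring_element)
  if (!(probability_threshold > 0 && probability_threshold < 1))
    lm_abort("probability_threshold must lie strictly in (0, 1)",
             "lesionmap_error_bad_params")
  if (closing_radius_mm <= 0)
    lm_abort("closing_radius_mm must be positive", "lesionmap_error_bad_params")
  structure(list(probability_threshold = probability_threshold,
                 closing_radius_mm = closing_radius_mm,
                 structuring_element = structuring_element,
                 fill_holes = fill_holes),
            class = "parenchyma_params")
}

structuring_offsets <- function(radius_mm, spacing, element = "ball") {
  rv <- pmax(0L, as.integer(floor(radius_mm / spacing)))
  g <- as.matrix(expand.grid(i = -rv[1]:rv[1], j = -rv[2]:rv[2],
                             k = -rv[3]:rv[3]))
  if (element == "ball") {
    d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
      (g[, 3] * spacing[3])^2
    g <- g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  }
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g
}

# Minkowski dilation/erosion by a symmetric structuring element given as
# integer voxel offsets. Voxels outside the array are treated as background,
# so erosion fails near the border unless the element fits inside.
dilate_mask <- function(values, offsets) {
  d <- dim(values)
  centers <- which(values != 0) - 1L
  if (length(centers) == 0L) return(array(0, d))
  cmat <- cbind(centers %% d[1],
                (centers %/% d[1]) %% d[2],
                centers %/% (d[1] * d[2]))
  storage.mode(cmat) <- "integer"
  counts <- cpp_count_map(d, offsets, cmat)
  array(as.numeric(counts > 0), d)
}

erode_mask <- function(values, offsets) {
  d <- dim(values)
  centers <- which(values != 0) - 1L
  out <- array(0, d)
  if (length(centers) == 0L) return(out)
  cmat <- cbind(centers %% d[1],
                (centers %/% d[1]) %% d[2],
                centers %/% (d[1] * d[2]))
  storage.mode(cmat) <- "integer"
  counts <- cpp_count_map(d, offsets, cmat)
  # a voxel survives erosion iff every structuring position hits foreground
  out[counts == nrow(offsets)] <- 1
  out
}

close_mask <- function(values, offsets) {
  erode_mask(dilate_mask(values, offsets), offsets)
}

#' Build the brain parenchymal mask
#'
#' Thresholds the voxel-wise sum of the gray- and white-matter probability
#' maps at `probability_threshold` (inclusive), applies a morphological
#' closing with the configured structuring element, and finally flood-fills
#' any remaining fully enclosed cavities (ventricles) from the volume border.
#' The output is a binary mask on the input grid and always contains the raw
#' thresholded mask.
#'
#' @param gm,wm Gray- and white-matter probability maps (`volume_grid`s on a
#'   common grid, values in \[0, 1\]).
#' @param params A [parenchyma_params()] object.
#' @return A binary `volume_grid`.
#' @export
build_parenchyma_mask <- function(gm, wm, params = parenchyma_params()) {
  assert_compatible(list(gm, wm))
  assert_probability(gm, "gm map")
  assert_probability(wm, "wm map")
  raw <- array(as.numeric(gm$values + wm$values >=
                            params$probability_threshold),
               dim(gm$values))
  off <- structuring_offsets(params$closing_radius_mm, voxel_spacing(gm),
                             params$structuring_element)
  closed <- close_mask(raw, off)
  closed[raw == 1] <- 1 # closing is extensive; guard against border clipping
  if (params$fill_holes) {
    filled <- cpp_fill_holes(as.integer(closed), dim(closed))
    closed <- array(as.numeric(filled), dim(closed))
  }
  volume_grid(closed, gm$affine)
}
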