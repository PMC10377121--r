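#' Sphere offset template
#'
#' Integer voxel offsets whose world-mm distance from the origin voxel center
#' is at most `radius_mm` (closed ball), for the given per-axis spacing.
#' Frequency maps are built by stamping this template at each center.
#'
#' @param radius_mm Sphere radius in mm (> 0).
#' @param spacing Per-axis voxel spacing in mm (length 3).
#' @return Integer matrix with 3 columns (di, dj, dk).
#' @export
sphere_offsets <- function(radius_mm, spacing) {
  if (radius_mm <= 0)
    lm_abort("radius_mm must be positive", "lesionmap_error_bad_params")
  structuring_offsets(radius_mm, spacing, "ball")
}

#' Binary sphere indicator around a voxel
#'
#' Voxel = 1 iff the world-mm distance from its center to the given center
#' voxel's position is <= `radius_mm`; clipped at the volume boundary.
#'
#' @param center_index 0-based integer triple.
#' @param radius_mm Sphere radius in mm.
#' @param grid Reference `volume_grid`.
#' @return Binary `volume_grid`.
#' @export
sphere_indicator <- function(center_index, radius_mm, grid) {
  center_index <- check_index_range(grid, center_index)
  off <- sphere_offsets(radius_mm, voxel_spacing(grid))
  counts <- cpp_count_map(dim(grid$values), off,
                          matrix(center_index, nrow = 1L))
  volume_grid(array(as.numeric(counts > 0), dim(grid$values)), grid$affine)
}

#' Build a tumor frequency map
#'
#' The voxel-wise sum of sphere indicators around all tumor centers of a
#' group, normalized by the group's tumor count: the value at a voxel is the
#' fraction of the group's tumors whose center lies within `radius_mm` of it.
#'
#' @param centers n x 3 integer matrix of 0-based center voxel indices (or a
#'   single triple).
#' @param radius_mm Sphere radius in mm (default 20, the standard kernel for
#'   metastasis frequency mapping).
#' @param grid Reference `volume_grid`.
#' @param group Optional group label stored with the map.
#' @return A `frequency_map`: list with `grid` (`volume_grid` of values in
#'   \[0, 1\]), `group`, `n_tumors`, `radius_mm`.
#' @export
build_frequency_map <- function(centers, radius_mm = 20, grid,
                                group = NA_character_) {
  if (!is.matrix(centers)) centers <- matrix(centers, nrow = 1L)
  if (nrow(centers) == 0L)
    lm_abort("empty center list", "lesionmap_error_empty_input")
  storage.mode(centers) <- "integer"
  d <- dim(grid$values)
  if (any(centers < 0L) || any(centers >= matrix(d, nrow(centers), 3,
                                                 byrow = TRUE)))
    lm_abort("center index out of range", "lesionmap_error_index_out_of_range")
  off <- sphere_offsets(radius_mm, voxel_spacing(grid))
  counts <- cpp_count_map(d, off, centers)
  structure(list(
    grid = volume_grid(array(counts / nrow(centers), d), grid$affine),
    group = group, n_tumors = nrow(centers), radius_mm = radius_mm
  ), class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("<frequency_map> group=%s, n_tumors=%d, radius=%g mm, max=%.4f\n",
              x$group, x$n_tumors, x$radius_mm, max(x$grid$values)))
  invisible(x)
}

#' Between-group difference map
#'
#' Voxel-wise difference a - b of two frequency maps built with the same
#' radius on a common grid; values lie in \[-1, 1\]. Difference maps are
#' descriptive (no significance testing is attached to them).
#'
#' @param a,b `frequency_map`s.
#' @return A `volume_grid`.
#' @export
difference_map <- function(a, b) {
  if (!isTRUE(all.equal(a$radius_mm, b$radius_mm)))
    lm_abort("frequency maps built with different radii",
             "lesionmap_error_incompatible_grids")
  assert_compatible(list(a$grid, b$grid))
  volume_grid(a$grid$values - b$grid$values, a$grid$affine)
}
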