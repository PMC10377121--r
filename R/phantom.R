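#' Synthetic brain phantom specification
#'
#' Describes an ellipsoidal brain phantom: grid geometry, outer semi-axes, a
#' smooth gray-matter shell over a white-matter core with a gray/white
#' junction, and an optional ellipsoidal ventricle cavity filled with CSF.
#' A thin band of voxels at the shell/core interface carries a gray-matter
#' probability exactly equal to `junction_gm`, so junction-seeded lesions
#' have an exactly recoverable GMD; the band emulates the gray-white
#' junction where metastatic emboli preferentially lodge.
#'
#' @param shape Grid dimensions (3 positive integers).
#' @param voxel_size_mm Isotropic voxel edge length (mm).
#' @param semi_axes_mm Outer ellipsoid semi-axes (mm); must fit in the grid.
#' @param junction_gm Gray-matter probability on the junction band (default
#'   0.6).
#' @param junction_rho Normalized ellipsoidal radius of the junction
#'   (0 = center, 1 = surface).
#' @param shell_width Logistic width of the gray-matter profile in normalized
#'   radius units.
#' @param gm_max Peak cortical gray-matter probability.
#' @param tissue_total gm + wm inside the parenchyma (< 1).
#' @param junction_band Half-width (in probability) of the exact-value
#'   junction band.
#' @param ventricle `NULL`, or a list with `semi_axes_mm` and `offset_mm`
#'   describing the CSF cavity.
#' @param seed Seed recorded alongside the settings (the phantom itself is
#'   deterministic).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), voxel_size_mm = 2,
                         semi_axes_mm = c(52, 58, 48), junction_gm = 0.6,
                         junction_rho = 0.7, shell_width = 0.06,
                         gm_max = 0.92, tissue_total = 0.98,
                         junction_band = 0.015,
                         ventricle = list(semi_axes_mm = c(12, 18, 10),
                                          offset_mm = c(0, 6, 2)),
                         seed = 1L) {
  extents <- shape * voxel_size_mm / 2
  if (any(semi_axes_mm >= extents))
    lm_abort("ellipsoid semi-axes exceed the grid half-extents",
             "lesionmap_error_bad_params")
  if (junction_gm <= 0 || junction_gm >= gm_max)
    lm_abort("junction_gm must lie in (0, gm_max)",
             "lesionmap_error_bad_params")
  structure(list(shape = as.integer(shape), voxel_size_mm = voxel_size_mm,
                 semi_axes_mm = semi_axes_mm, junction_gm = junction_gm,
                 junction_rho = junction_rho, shell_width = shell_width,
                 gm_max = gm_max, tissue_total = tissue_total,
                 junction_band = junction_band, ventricle = ventricle,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic brain phantom
#'
#' Builds gray-matter, white-matter and CSF probability maps plus the true
#' parenchymal mask (the filled outer ellipsoid). The gray-matter probability
#' rises logistically from the core to `gm_max` at the cortex, passing
#' exactly through `junction_gm` on the junction band; white matter is the
#' complement up to `tissue_total`; the ventricle cavity is pure CSF. The
#' world origin is at the grid center.
#'
#' @param spec A [phantom_spec()].
#' @return List with `gm`, `wm`, `csf`, `parenchyma` (`volume_grid`s),
#'   `junction_voxels` (0-based linear indices of the band, inside the
#'   parenchyma and outside the ventricle), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  d <- spec$shape
  vs <- spec$voxel_size_mm
  affine <- diag(c(rep(vs, 3), 1))
  affine[1:3, 4] <- -(d - 1) / 2 * vs

  ax <- ((0:(d[1] - 1)) - (d[1] - 1) / 2) * vs
  ay <- ((0:(d[2] - 1)) - (d[2] - 1) / 2) * vs
  az <- ((0:(d[3] - 1)) - (d[3] - 1) / 2) * vs
  x2 <- (ax / spec$semi_axes_mm[1])^2
  y2 <- (ay / spec$semi_axes_mm[2])^2
  z2 <- (az / spec$semi_axes_mm[3])^2
  rho <- sqrt(outer(outer(x2, y2, `+`), z2, `+`))

  parenchyma <- array(as.numeric(rho <= 1), d)

  rho0 <- spec$junction_rho -
    spec$shell_width * stats::qlogis(spec$junction_gm / spec$gm_max)
  gm <- spec$gm_max * stats::plogis((rho - rho0) / spec$shell_width)
  band <- abs(gm - spec$junction_gm) <= spec$junction_band
  gm[band] <- spec$junction_gm
  gm[parenchyma == 0] <- 0
  wm <- pmax(spec$tissue_total - gm, 0)
  wm[parenchyma == 0] <- 0
  csf <- array(0, d)

  if (!is.null(spec$ventricle)) {
    vx2 <- ((ax - spec$ventricle$offset_mm[1]) /
              spec$ventricle$semi_axes_mm[1])^2
    vy2 <- ((ay - spec$ventricle$offset_mm[2]) /
              spec$ventricle$semi_axes_mm[2])^2
    vz2 <- ((az - spec$ventricle$offset_mm[3]) /
              spec$ventricle$semi_axes_mm[3])^2
    cavity <- outer(outer(vx2, vy2, `+`), vz2, `+`) <= 1
    gm[cavity] <- 0
    wm[cavity] <- 0
    csf[cavity & parenchyma == 1] <- 1
  }

  junction <- which(gm == spec$junction_gm & parenchyma == 1) - 1L

  list(gm = volume_grid(gm, affine), wm = volume_grid(wm, affine),
       csf = volume_grid(csf, affine),
       parenchyma = volume_grid(parenchyma, affine),
       junction_voxels = junction, spec = spec)
}
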