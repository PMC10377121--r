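#' Construct a volume grid
#'
#' A `volume_grid` is the universal carrier for all volumetric data in the
#' package: a 3D numeric array plus a 4x4 affine mapping 0-based voxel indices
#' to world coordinates in mm (the convention used by the NIfTI sform). Binary
#' masks and probability maps are `volume_grid`s with restricted value ranges.
#'
#' @param values 3D numeric array.
#' @param affine 4x4 voxel-index-to-world-mm matrix; must be invertible.
#' @return An object of class `volume_grid` with elements `values` and
#'   `affine`.
#' @export
volume_grid <- function(values, affine = diag(4)) {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    lm_abort("`values` must be a 3D array", "lesionmap_error_non_3d")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    lm_abort("`affine` must be a 4x4 matrix", "lesionmap_error_bad_affine")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    lm_abort("`affine` upper 3x3 block is singular",
             "lesionmap_error_bad_affine")
  structure(list(values = values, affine = affine), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(voxel_spacing(x), 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Voxel spacing and voxel volume
#'
#' Per-axis physical voxel edge lengths (mm), taken as the column norms of the
#' affine's 3x3 block, and the physical voxel volume (mm^3) as its absolute
#' determinant.
#'
#' @param vol A `volume_grid`.
#' @return `voxel_spacing`: length-3 numeric (mm). `voxel_volume_mm3`: scalar.
#' @export
voxel_spacing <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' @rdname voxel_spacing
#' @export
voxel_volume_mm3 <- function(vol) {
  abs(det(vol$affine[1:3, 1:3]))
}

is_binary_values <- function(values) {
  all(values == 0 | values == 1)
}

assert_binary <- function(vol, what = "mask") {
  if (!is_binary_values(vol$values))
    lm_abort(sprintf("%s is not binary (values other than 0/1 present)", what),
             "lesionmap_error_not_binary")
  invisible(vol)
}

assert_probability <- function(vol, what = "probability map") {
  rng <- range(vol$values)
  if (rng[1] < 0 || rng[2] > 1)
    lm_abort(sprintf("%s has values outside [0, 1]", what),
             "lesionmap_error_not_probability")
  invisible(vol)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/NIfTI-2 image as stored: no resampling, no reorientation.
#' The affine is the image's xform (sform/qform), which maps 0-based voxel
#' indices to world mm.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `volume_grid`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    lm_abort(sprintf("file not found: %s", path),
             "lesionmap_error_missing_file")
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    lm_abort(sprintf("unreadable NIfTI image: %s (%s)", path,
                     conditionMessage(e)),
             "lesionmap_error_unreadable"))
  arr <- as.array(img)
  d <- dim(arr)
  arr <- array(as.vector(arr), d) # drop NIfTI attributes from the data
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(arr, d[1:3])
  } else if (length(d) != 3L) {
    lm_abort(sprintf("non-3D image (%d dimensions): %s", length(d), path),
             "lesionmap_error_non_3d")
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume_grid(arr, aff)
}

#' Write a NIfTI volume
#'
#' @param vol A `volume_grid`.
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    lm_abort(sprintf("directory does not exist: %s", dirname(path)),
             "lesionmap_error_unwritable")
  img <- RNifti::asNifti(vol$values)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  # the header pixdim must agree with the affine scale or the scale is lost
  # when the image is serialized
  img <- RNifti::`pixdim<-`(img, voxel_spacing(vol))
  RNifti::writeNifti(img, path)
  invisible(path)
}

check_index_range <- function(vol, index) {
  index <- as.integer(round(index))
  d <- dim(vol$values)
  if (length(index) != 3L || any(index < 0L) || any(index > d - 1L))
    lm_abort(sprintf("voxel index (%s) out of range for grid %s",
                     paste(index, collapse = ","),
                     paste(d, collapse = "x")),
             "lesionmap_error_index_out_of_range")
  index
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based triples; world coordinates are mm in the affine's
#' frame. `voxel_to_world` applies the affine to the homogeneous index;
#' `world_to_voxel` applies the inverse and rounds to the nearest voxel.
#'
#' @param vol A `volume_grid`.
#' @param index Integer triple (0-based), or an n x 3 matrix of triples.
#' @param world Numeric triple (mm), or an n x 3 matrix.
#' @return A numeric triple / n x 3 matrix (mm), or an integer triple /
#'   n x 3 integer matrix.
#' @export
voxel_to_world <- function(vol, index) {
  if (is.matrix(index)) {
    apply(index, 1L, function(ix) voxel_to_world(vol, ix)) |> t()
  } else {
    index <- check_index_range(vol, index)
    as.numeric(vol$affine %*% c(index, 1))[1:3]
  }
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, world) {
  if (is.matrix(world)) {
    t(apply(world, 1L, function(w) world_to_voxel(vol, w)))
  } else {
    v <- as.numeric(solve(vol$affine) %*% c(world, 1))[1:3]
    as.integer(round(v))
  }
}

#' Enforce the common-grid contract
#'
#' All volumes entering a joint analysis must live on one grid: identical
#' shapes and elementwise-equal affines within `tolerance_mm`. Violations
#' raise an error naming the offending pair.
#'
#' @param vols List of `volume_grid`s (at least one).
#' @param tolerance_mm Elementwise affine tolerance in mm (default 1e-3).
#' @return Invisibly `TRUE` on success.
#' @export
assert_compatible <- function(vols, tolerance_mm = 1e-3) {
  if (length(vols) < 1L)
    lm_abort("need at least one volume", "lesionmap_error_empty_input")
  ref <- vols[[1L]]
  for (i in seq_along(vols)[-1L]) {
    v <- vols[[i]]
    if (!identical(dim(ref$values), dim(v$values)))
      lm_abort(sprintf(
        "incompatible grids: volumes 1 and %d have shapes %s vs %s", i,
        paste(dim(ref$values), collapse = "x"),
        paste(dim(v$values), collapse = "x")),
        "lesionmap_error_incompatible_grids")
    if (max(abs(ref$affine - v$affine)) > tolerance_mm)
      lm_abort(sprintf(
        "incompatible grids: affines of volumes 1 and %d differ by up to %g mm",
        i, max(abs(ref$affine - v$affine))),
        "lesionmap_error_incompatible_grids")
  }
  invisible(TRUE)
}

# Lightweight structural fingerprint used for provenance checks between
# calibration objects; not a cryptographic hash.
grid_fingerprint <- function(vol) {
  c(dim(vol$values), sum(vol$values), round(sum(vol$affine), 6))
}
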