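#' Intensity volume
#'
#' Container for a 3D scalar image grid together with its voxel spacing.
#' All geometry in the package is computed in voxel index space (1-based,
#' axial slices along the third axis) and converted to millimetres via
#' `spacing`. The third spacing component is the centre-to-centre slice
#' spacing, i.e. slice thickness plus any inter-slice gap (a 5 mm slice
#' with a 1 mm gap has `dz = 6`).
#'
#' @param data numeric 3D array of non-negative, finite intensities.
#' @param spacing numeric length-3 vector `(dx, dy, dz)` in mm, all > 0.
#' @param id free-text case identifier.
#'
#' @return An object of class `pvs_volume`: a list with elements `data`,
#'   `spacing` and `id`.
#' @examples
#' v <- pvs_volume(array(runif(27), c(3, 3, 3)), spacing = c(0.47, 0.47, 6))
#' voxel_volume_mm3(v)
#' @export
pvs_volume <- function(data, spacing, id = "case") {
  if (!is.array(data) || length(dim(data)) != 3L)
    pvs_stop("not_3d", "`data` must be a 3D array")
  if (any(dim(data) < 1L))
    pvs_stop("not_3d", "every axis must have extent >= 1")
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    pvs_stop("bad_intensity", "intensities must be finite and non-missing")
  if (any(data < 0))
    pvs_stop("bad_intensity", "intensities must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    pvs_stop("bad_spacing", "`spacing` must be three positive values (mm)")
  structure(list(data = data, spacing = spacing, id = as.character(id)[1]),
            class = "pvs_volume")
}

#' @export
print.pvs_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pvs_volume> %s: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm (%.4f mm^3/voxel)\n",
              x$id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3], voxel_volume_mm3(x)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel volume in cubic millimetres
#'
#' @param x a `pvs_volume`, or a numeric length-3 spacing vector in mm.
#' @return `dx * dy * dz` in mm^3.
#' @examples
#' voxel_volume_mm3(c(0.47, 0.47, 6)) # 1.3254
#' @export
voxel_volume_mm3 <- function(x) {
  sp <- if (inherits(x, "pvs_volume")) x$spacing else as.numeric(x)
  if (length(sp) != 3L || any(sp <= 0))
    pvs_stop("bad_spacing", "spacing must be three positive values (mm)")
  prod(sp)
}

# Extract one axial slice (matrix) from a volume; 1-based index.
get_slice <- function(volume, slice_index) {
  d <- dim(volume$data)
  if (slice_index < 1L || slice_index > d[3])
    pvs_stop("bad_slice", sprintf("slice_index %d outside 1..%d", slice_index, d[3]))
  volume$data[, , slice_index]
}
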