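# Bilateral ovoid basal-ganglia regions of interest. The assessment is
# restricted to one ovoid per hemisphere on a single axial slice; elongated
# PVS outside these regions rate too unreliably to count. For patient data
# a hand-drawn mask file is preferred; the parametric ellipse spec serves
# phantoms and scripted use.

#' Ovoid ROI specification
#'
#' Parameters of two elliptical ("ovoid") regions, one per hemisphere, on a
#' chosen axial slice. Coordinates are 1-based voxel indices.
#'
#' @param slice_index axial slice the ROI lives on (1-based).
#' @param left_center,right_center `(row, col)` ellipse centres.
#' @param semi_axes `(a, b)`: semi-axis along rows and along columns, in
#'   voxels (before rotation).
#' @param rotation in-plane rotation in degrees (anticlockwise).
#' @return A list of class `pvs_roi_spec`.
#' @export
roi_spec <- function(slice_index, left_center, right_center,
                     semi_axes, rotation = 0) {
  if (any(semi_axes <= 0))
    pvs_stop("bad_params", "semi-axes must be positive")
  structure(list(slice_index = as.integer(slice_index),
                 left_center = as.numeric(left_center),
                 right_center = as.numeric(right_center),
                 semi_axes = as.numeric(semi_axes),
                 rotation = as.numeric(rotation)),
            class = "pvs_roi_spec")
}

# Logical membership of every pixel of an nr x nc grid in one rotated
# ellipse. Membership is decided at pixel centres (integer coordinates).
.ellipse_mask <- function(slice_shape, center, semi_axes, rotation) {
  nr <- slice_shape[1]; nc <- slice_shape[2]
  r <- matrix(seq_len(nr), nr, nc) - center[1]
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  th <- rotation * pi / 180
  u <- cos(th) * r + sin(th) * c
  v <- -sin(th) * r + cos(th) * c
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}

#' Build a bilateral ovoid ROI mask
#'
#' Rasterises the two ellipses of a [roi_spec] onto a slice grid. A pixel
#' belongs to an ovoid iff its centre satisfies the rotated-ellipse
#' inequality \eqn{(u/a)^2 + (v/b)^2 \le 1}. The two ovoids must lie fully
#' inside the slice and must not touch or overlap.
#'
#' @param slice_shape `(rows, cols)` of the working slice.
#' @param spec a [roi_spec].
#' @return An object of class `pvs_roi`: list with `mask` (logical matrix),
#'   `n_components` (always 2) and `spec`.
#' @examples
#' roi <- make_ovoid_roi(c(96, 96), roi_spec(1, c(48, 28), c(48, 68), c(20, 12)))
#' sum(roi$mask)
#' @export
make_ovoid_roi <- function(slice_shape, spec) {
  stopifnot(inherits(spec, "pvs_roi_spec"))
  for (ctr in list(spec$left_center, spec$right_center)) {
    if (ctr[1] < 1 || ctr[1] > slice_shape[1] ||
        ctr[2] < 1 || ctr[2] > slice_shape[2])
      pvs_stop("roi_out_of_bounds", "ellipse centre outside the slice")
    ext <- max(spec$semi_axes)
    if (ctr[1] - ext < 1 || ctr[1] + ext > slice_shape[1] ||
        ctr[2] - ext < 1 || ctr[2] + ext > slice_shape[2])
      pvs_stop("roi_out_of_bounds", "ellipse extent exceeds the slice bounds")
  }
  left <- .ellipse_mask(slice_shape, spec$left_center, spec$semi_axes, spec$rotation)
  right <- .ellipse_mask(slice_shape, spec$right_center, spec$semi_axes, spec$rotation)
  if (any(left & right))
    pvs_stop("roi_overlap", "the two ovoids overlap")
  mask <- left | right
  if (length(label_objects(mask, connectivity = 8)) != 2L)
    pvs_stop("roi_overlap", "the two ovoids touch: ROI must have exactly 2 components")
  structure(list(mask = mask, n_components = 2L, spec = spec),
            class = "pvs_roi")
}

# Coerce pvs_roi or plain logical matrix to a logical matrix.
as_roi_mask <- function(roi) {
  m <- if (inherits(roi, "pvs_roi")) roi$mask else roi
  if (!is.matrix(m)) pvs_stop("bad_roi", "ROI must be a logical matrix or pvs_roi")
  matrix(as.logical(m), nrow = nrow(m))
}

#' Validate an ROI mask
#'
#' Reports the connected-component structure of a binary ROI mask and flags
#' masks that do not consist of exactly two regions (one per hemisphere).
#'
#' @param mask logical matrix (or [make_ovoid_roi] result).
#' @param brain_mask optional logical matrix; if given, the report includes
#'   the fraction of ROI pixels inside it.
#' @return A list with `n_components`, `component_areas` (pixel counts),
#'   `ok` (exactly two components) and, if `brain_mask` was supplied,
#'   `brain_coverage`.
#' @export
validate_roi <- function(mask, brain_mask = NULL) {
  m <- as_roi_mask(mask)
  if (!any(m)) pvs_stop("empty_mask", "ROI mask is empty")
  comps <- label_objects(m, connectivity = 8)
  out <- list(n_components = length(comps),
              component_areas = vapply(comps, nrow, integer(1)),
              ok = length(comps) == 2L)
  if (!is.null(brain_mask)) {
    if (!all(dim(brain_mask) == dim(m)))
      pvs_stop("shape_mismatch", "brain mask shape differs from ROI")
    out$brain_coverage <- sum(m & brain_mask) / sum(m)
  }
  out
}
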