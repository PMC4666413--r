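# Core PVS detection on the adjusted basal-ganglia slice: pick a threshold
# from the case's image characteristics, binarise within the ROI, label
# connected components, drop objects outside the PVS size range (< 3 mm
# equivalent diameter in cross-section), and report count and volume.

#' Case image characteristics
#'
#' Operator-assessed flags describing the T2W appearance of a case, used by
#' [select_threshold()] to pick among the three canonical thresholds.
#'
#' @param scattered_pvs PVS are scattered rather than grouped.
#' @param uniform_background visually normal, uniform background intensity.
#' @param few_focal_lesions few focal lesions (WMH, lacunes).
#' @param grouped_pvs PVS appear grouped / coalescent.
#' @param high_background high background signal (e.g. diffuse WMH).
#' @param many_lesions many other lesions (WMH, lacunes, mineral deposits).
#' @param poor_quality poor scan quality, e.g. movement artefact.
#' @return A list of class `pvs_case_chars`.
#' @export
case_characteristics <- function(scattered_pvs = FALSE,
                                 uniform_background = FALSE,
                                 few_focal_lesions = FALSE,
                                 grouped_pvs = FALSE,
                                 high_background = FALSE,
                                 many_lesions = FALSE,
                                 poor_quality = FALSE) {
  flags <- list(scattered_pvs = scattered_pvs,
                uniform_background = uniform_background,
                few_focal_lesions = few_focal_lesions,
                grouped_pvs = grouped_pvs,
                high_background = high_background,
                many_lesions = many_lesions,
                poor_quality = poor_quality)
  if (!all(vapply(flags, is.logical, logical(1))))
    pvs_stop("bad_params", "all characteristics must be logical flags")
  structure(lapply(flags, isTRUE), class = "pvs_case_chars")
}

.THRESHOLD_FRACTIONS <- c(low = 0.075, medium = 0.1125, high = 0.15)

#' Threshold policy
#'
#' One of the three canonical intensity thresholds, expressed as a fraction
#' of the maximum signal intensity of the adjusted (combined) slice: low
#' 7.5%, medium 11.25%, high 15% or above. `custom` accepts any fraction.
#'
#' @param level `"low"`, `"medium"`, `"high"` or `"custom"`.
#' @param fraction_of_max required for `custom`; for `high` it may override
#'   the default 0.15 with any value >= 0.15.
#' @return A list of class `pvs_threshold_policy`.
#' @export
threshold_policy <- function(level = c("low", "medium", "high", "custom"),
                             fraction_of_max = NULL) {
  level <- match.arg(level)
  if (level == "custom") {
    if (is.null(fraction_of_max) || fraction_of_max <= 0 || fraction_of_max > 1)
      pvs_stop("bad_params", "custom policy needs fraction_of_max in (0, 1]")
    f <- fraction_of_max
  } else {
    f <- unname(.THRESHOLD_FRACTIONS[level])
    if (level == "high" && !is.null(fraction_of_max)) {
      if (fraction_of_max < .THRESHOLD_FRACTIONS["high"])
        pvs_stop("bad_params", "high threshold fraction must be >= 0.15")
      f <- fraction_of_max
    } else if (level != "high" && !is.null(fraction_of_max) &&
               fraction_of_max != f) {
      pvs_stop("bad_params", sprintf("%s threshold fraction is fixed at %g", level, f))
    }
  }
  structure(list(level = level, fraction_of_max = f),
            class = "pvs_threshold_policy")
}

#' Select a threshold from case characteristics
#'
#' Applies the decision rules: the high threshold whenever the case has
#' grouped PVS, a high background signal, many other lesions, or poor scan
#' quality; the low threshold when it has scattered PVS *and* a uniform
#' background *and* few focal lesions; the medium threshold otherwise.
#'
#' @param chars a [case_characteristics] object.
#' @return A [threshold_policy].
#' @examples
#' select_threshold(case_characteristics(scattered_pvs = TRUE,
#'   uniform_background = TRUE, few_focal_lesions = TRUE))$level # "low"
#' @export
select_threshold <- function(chars) {
  stopifnot(inherits(chars, "pvs_case_chars"))
  if (chars$grouped_pvs || chars$high_background ||
      chars$many_lesions || chars$poor_quality)
    return(threshold_policy("high"))
  if (chars$scattered_pvs && chars$uniform_background && chars$few_focal_lesions)
    return(threshold_policy("low"))
  threshold_policy("medium")
}

#' Apply an intensity threshold inside the ROI
#'
#' A pixel is a PVS candidate iff it lies inside the ROI, is not covered by
#' the exclusion mask, and its adjusted intensity is greater than or equal
#' to `fraction_of_max * out_max` (ties included).
#'
#' @param adjusted_slice numeric matrix on the `[0, out_max]` scale (the
#'   output of the adjustment pipeline).
#' @param roi a [make_ovoid_roi] result or logical matrix.
#' @param policy a [threshold_policy].
#' @param exclusion_mask optional logical matrix of manually excluded
#'   pixels (lacunes, infarcts, artefacts).
#' @param out_max the normalised intensity ceiling.
#' @return Logical candidate matrix.
#' @export
apply_threshold <- function(adjusted_slice, roi, policy,
                            exclusion_mask = NULL, out_max = 255) {
  roi_m <- as_roi_mask(roi)
  if (!all(dim(adjusted_slice) == dim(roi_m)))
    pvs_stop("shape_mismatch", "slice and ROI shapes differ")
  if (!any(roi_m)) pvs_stop("empty_mask", "ROI mask is empty")
  keep <- roi_m & adjusted_slice >= policy$fraction_of_max * out_max
  if (!is.null(exclusion_mask)) {
    if (!all(dim(exclusion_mask) == dim(adjusted_slice)))
      pvs_stop("shape_mismatch", "exclusion mask shape differs from slice")
    keep <- keep & !exclusion_mask
  }
  keep
}

#' Label connected components of a binary mask
#'
#' Partitions the foreground pixels of a 2D mask into maximal connected
#' components under 4- or 8-neighbour connectivity, by iterative frontier
#' expansion (vectorised flood fill).
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return A list of components; each is a two-column integer matrix of
#'   `(row, col)` pixel coordinates. The empty mask yields an empty list.
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 1] <- m[2, 2] <- TRUE
#' length(label_objects(m, 4)) # 2: diagonal pixels are separate
#' length(label_objects(m, 8)) # 1
#' @export
label_objects <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8))
    pvs_stop("bad_params", "connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(list())
  offs <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8)
    offs <- rbind(offs, c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  lab <- integer(nr * nc)
  cur <- 0L
  comps <- list()
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    member <- s
    frontier <- s
    while (length(frontier)) {
      fr <- (frontier - 1L) %% nr + 1L
      fc <- (frontier - 1L) %/% nr + 1L
      nb <- integer(0)
      for (j in seq_len(nrow(offs))) {
        r2 <- fr + offs[j, 1L]; c2 <- fc + offs[j, 2L]
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
        if (any(ok)) nb <- c(nb, (c2[ok] - 1L) * nr + r2[ok])
      }
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      member <- c(member, nb)
      frontier <- nb
    }
    comps[[cur]] <- cbind(row = (member - 1L) %% nr + 1L,
                          col = (member - 1L) %/% nr + 1L)
  }
  comps
}

#' Object size filter
#'
#' PVS are at most 3 mm across in cross-section; larger hyperintensities
#' (lacunes, infarcts) are rejected by equivalent diameter, which adapts to
#' pixel spacing. A minimum pixel count can suppress single-pixel noise.
#'
#' @param min_voxels minimum in-plane pixel count (default 1: keep all).
#' @param max_equivalent_diameter_mm maximum equivalent diameter of the
#'   circle with the object's area (default 3 mm).
#' @return A list of class `pvs_size_filter`.
#' @export
size_filter <- function(min_voxels = 1L, max_equivalent_diameter_mm = 3.0) {
  if (min_voxels < 1L || max_equivalent_diameter_mm <= 0)
    pvs_stop("bad_params", "min_voxels >= 1 and positive max diameter required")
  structure(list(min_voxels = as.integer(min_voxels),
                 max_equivalent_diameter_mm = max_equivalent_diameter_mm),
            class = "pvs_size_filter")
}

#' Filter components by size and build the object table
#'
#' Keeps components with `voxel_count >= min_voxels` and equivalent
#' diameter `2 * sqrt(voxel_count * dx * dy / pi)` at most the maximum,
#' and converts each survivor to one row of the per-object table (area,
#' equivalent diameter, centroid, volume in ml; the slice volume uses
#' `dx * dy * dz`).
#'
#' @param components list of pixel-coordinate matrices from
#'   [label_objects()].
#' @param filter a [size_filter].
#' @param spacing `(dx, dy, dz)` voxel spacing in mm.
#' @return A data frame with columns `label`, `voxel_count`, `area_mm2`,
#'   `equivalent_diameter_mm`, `centroid_row`, `centroid_col`, `volume_ml`.
#' @export
filter_objects <- function(components, filter = size_filter(),
                           spacing = c(0.47, 0.47, 6)) {
  if (any(spacing <= 0)) pvs_stop("bad_spacing", "spacing must be positive")
  if (length(components) == 0L) return(empty_object_table())
  px_area <- spacing[1] * spacing[2]
  n <- vapply(components, nrow, integer(1))
  diam <- 2 * sqrt(n * px_area / pi)
  keep <- which(n >= filter$min_voxels &
                diam <= filter$max_equivalent_diameter_mm)
  if (length(keep) == 0L) return(empty_object_table())
  data.frame(
    label = seq_along(keep),
    voxel_count = n[keep],
    area_mm2 = n[keep] * px_area,
    equivalent_diameter_mm = diam[keep],
    centroid_row = vapply(components[keep], function(p) mean(p[, 1]), numeric(1)),
    centroid_col = vapply(components[keep], function(p) mean(p[, 2]), numeric(1)),
    volume_ml = n[keep] * prod(spacing) / 1000
  )
}

#' Count and total volume of segmented objects
#'
#' @param objects per-object table from [filter_objects()].
#' @param spacing voxel spacing in mm (used only for validation).
#' @return A list with `count`, `total_volume_ml` and `per_object_volume_ml`.
#' @export
quantify <- function(objects, spacing = c(0.47, 0.47, 6)) {
  if (any(spacing <= 0)) pvs_stop("bad_spacing", "spacing must be positive")
  list(count = nrow(objects),
       total_volume_ml = sum(objects$volume_ml),
       per_object_volume_ml = objects$volume_ml)
}

#' Segment perivascular spaces on one axial slice
#'
#' Runs the full pipeline on the chosen basal-ganglia slice: saturating
#' rescale, quadratic self-combination, ROI-restricted thresholding,
#' connected-component labelling, size filtering, and quantification.
#' The threshold comes either from an explicit `policy` or from the
#' decision rules applied to `characteristics`. Difficult cases are
#' handled by re-running with another threshold and/or an exclusion mask
#' covering lesions that mimic PVS.
#'
#' @param volume a [pvs_volume] (or a single-slice phantom).
#' @param slice_index axial slice to analyse (1-based).
#' @param roi a [make_ovoid_roi] result or logical matrix on that slice.
#' @param policy a [threshold_policy], or `NULL` to derive one from
#'   `characteristics`.
#' @param characteristics a [case_characteristics] object (required when
#'   `policy` is `NULL`).
#' @param filter a [size_filter].
#' @param exclusion_mask optional logical matrix of manually excluded pixels.
#' @param connectivity 4 or 8 (default 8: dots one pixel apart diagonally
#'   are one object).
#' @param params an [adjust_params] for the rescale stage.
#' @param adjust_domain `"slice"` (default) computes the saturation
#'   anchors from the analysed slice; `"volume"` computes them from the
#'   whole volume.
#' @return An object of class `pvs_segmentation`: the per-object table,
#'   `count`, `total_volume_ml`, the policy used, the adjusted slice, the
#'   candidate mask and full provenance.
#' @seealso [write_results()], [condense_score()], [truth_match()]
#' @export
pvs_segment <- function(volume, slice_index, roi,
                        policy = NULL, characteristics = NULL,
                        filter = size_filter(), exclusion_mask = NULL,
                        connectivity = 8, params = adjust_params(),
                        adjust_domain = c("slice", "volume")) {
  stopifnot(inherits(volume, "pvs_volume"))
  adjust_domain <- match.arg(adjust_domain)
  if (is.null(policy)) {
    if (is.null(characteristics))
      pvs_stop("bad_params", "supply either a threshold policy or case characteristics")
    policy <- select_threshold(characteristics)
  }
  stopifnot(inherits(policy, "pvs_threshold_policy"))
  slice <- get_slice(volume, slice_index)
  adjusted <- if (adjust_domain == "volume") {
    get_slice(saturate_rescale(volume, params), slice_index)
  } else {
    saturate_rescale(slice, params)
  }
  combined <- combine_self_product(adjusted, out_max = params$out_max)
  candidates <- apply_threshold(combined, roi, policy,
                                exclusion_mask = exclusion_mask,
                                out_max = params$out_max)
  comps <- label_objects(candidates, connectivity = connectivity)
  objects <- filter_objects(comps, filter = filter, spacing = volume$spacing)
  q <- quantify(objects, volume$spacing)
  structure(list(
    objects = objects,
    count = q$count,
    total_volume_ml = q$total_volume_ml,
    policy = policy,
    slice_index = slice_index,
    id = volume$id,
    spacing = volume$spacing,
    adjusted_slice = combined,
    candidate_mask = candidates,
    roi_mask = as_roi_mask(roi),
    provenance = list(
      saturation_fraction = params$saturation_fraction,
      gamma_rescale = params$gamma,
      gamma_combination = 2,
      out_max = params$out_max,
      adjust_domain = adjust_domain,
      connectivity = connectivity,
      min_voxels = filter$min_voxels,
      max_equivalent_diameter_mm = filter$max_equivalent_diameter_mm,
      threshold_level = policy$level,
      threshold_fraction = policy$fraction_of_max,
      exclusion_mask_used = !is.null(exclusion_mask),
      high_background = if (!is.null(characteristics))
        characteristics$high_background else FALSE,
      roi_clipped_objects_kept = TRUE
    )
  ), class = "pvs_segmentation")
}

#' @export
print.pvs_segmentation <- function(x, ...) {
  cat(sprintf("<pvs_segmentation> case %s, slice %d\n", x$id, x$slice_index))
  cat(sprintf("  threshold: %s (%.4g%% of max)\n",
              x$policy$level, 100 * x$policy$fraction_of_max))
  cat(sprintf("  PVS count: %d   total volume: %.4f ml   score: %d\n",
              x$count, x$total_volume_ml,
              condense_score(x$count, isTRUE(x$provenance$high_background))))
  invisible(x)
}

#' @export
summary.pvs_segmentation <- function(object, ...) {
  print(object)
  if (object$count > 0) {
    cat("  per-object equivalent diameter (mm):\n")
    print(summary(object$objects$equivalent_diameter_mm))
  }
  invisible(object)
}

#' @export
plot.pvs_segmentation <- function(x, ...) {
  graphics::image(x$adjusted_slice, col = grDevices::gray.colors(128),
                  axes = FALSE, asp = ncol(x$adjusted_slice) / nrow(x$adjusted_slice),
                  main = sprintf("%s: %d PVS (%s threshold)", x$id, x$count,
                                 x$policy$level), ...)
  nr <- nrow(x$adjusted_slice); nc <- ncol(x$adjusted_slice)
  graphics::contour(seq_len(nr) / nr, seq_len(nc) / nc,
                    x$roi_mask + 0, levels = 0.5, add = TRUE,
                    drawlabels = FALSE, col = "cyan")
  if (x$count > 0)
    graphics::points(x$objects$centroid_row / nr, x$objects$centroid_col / nc,
                     col = "red", cex = 1.5)
  invisible(x)
}
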