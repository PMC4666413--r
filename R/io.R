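#' Read a 3D image volume
#'
#' Reads a NIfTI-1 (`.nii`, `.nii.gz`) or Analyze 7.5 (`.hdr`/`.img`) file
#' into a [pvs_volume]. Voxel spacing is taken from the header `pixdim`
#' fields; intensities are returned exactly as stored (no rescaling is
#' applied here — the adjustment pipeline is the only intensity transform).
#'
#' @param path path to the image file.
#' @param id case identifier; defaults to the file name without extension.
#' @return A [pvs_volume].
#' @seealso [read_mask()], [write_volume()]
#' @export
read_volume <- function(path, id = NULL) {
  if (!file.exists(path))
    pvs_stop("missing_file", sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    pvs_stop("not_3d", sprintf("expected a 3D image, got %s axes",
                               if (is.null(d)) 1L else length(d)))
  sp <- RNifti::pixdim(img)[1:3]
  if (anyNA(sp) || any(sp <= 0))
    pvs_stop("bad_spacing", "header voxel dimensions absent or non-positive")
  if (is.null(id))
    id <- sub("\\.(nii(\\.gz)?|hdr|img)$", "", basename(path))
  pvs_volume(array(as.numeric(img), d), spacing = as.numeric(sp), id = id)
}

#' Write a volume to NIfTI or Analyze
#'
#' The header is built explicitly (float64 data, full 3D `dim`), so
#' single-slice volumes keep their third axis and slice spacing on disk.
#'
#' @param volume a [pvs_volume].
#' @param path output path (`.nii` or `.nii.gz`; `.hdr` writes Analyze 7.5).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pvs_volume"))
  stem <- sub("\\.(nii\\.gz|nii|hdr|img)$", "", path)
  if (grepl("\\.(hdr|img)$", path)) {
    img <- oro.nifti::anlz(volume$data, datatype = 64L)
    oro.nifti::pixdim(img)[2:4] <- volume$spacing
    oro.nifti::writeANALYZE(img, stem, gzipped = FALSE)
  } else {
    img <- oro.nifti::nifti(volume$data, datatype = 64L)
    oro.nifti::pixdim(img)[2:4] <- volume$spacing
    oro.nifti::writeNIfTI(img, stem, gzipped = grepl("\\.gz$", path))
  }
  invisible(path)
}

#' Read a binary mask
#'
#' Reads a mask image and returns a logical matrix for the requested axial
#' slice. Accepts 2D images or 3D images (from which `slice_index` is
#' taken). Voxels > 0.5 are foreground.
#'
#' @param path path to the mask image.
#' @param slice_index axial slice to extract when the image is 3D (1-based).
#' @return A logical matrix.
#' @export
read_mask <- function(path, slice_index = 1L) {
  if (!file.exists(path))
    pvs_stop("missing_file", sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  m <- if (length(d) == 2L) img[, ] else if (length(d) == 3L) {
    if (slice_index < 1L || slice_index > d[3])
      pvs_stop("bad_slice", sprintf("slice_index %d outside 1..%d", slice_index, d[3]))
    img[, , slice_index]
  } else pvs_stop("not_3d", "mask must be a 2D or 3D image")
  matrix(m > 0.5, nrow = nrow(m))
}

#' Write segmentation results
#'
#' Writes the per-object table as CSV and a JSON summary (case id, slice
#' index, threshold policy, count, total volume, condensed score and the
#' full provenance of the run).
#'
#' @param result a [pvs_segmentation][pvs_segment] object.
#' @param table_path output CSV path for the per-object table.
#' @param summary_path output JSON path for the run summary.
#' @return Invisibly, a list with both paths.
#' @export
write_results <- function(result, table_path, summary_path) {
  stopifnot(inherits(result, "pvs_segmentation"))
  utils::write.csv(result$objects, table_path, row.names = FALSE)
  summary <- list(
    id = result$id,
    slice_index = result$slice_index,
    threshold_level = result$policy$level,
    threshold_fraction = result$policy$fraction_of_max,
    count = result$count,
    total_volume_ml = result$total_volume_ml,
    score = condense_score(result$count,
                           isTRUE(result$provenance$high_background)),
    provenance = result$provenance
  )
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(table = table_path, summary = summary_path))
}

# Empty per-object table with the fixed column contract.
empty_object_table <- function() {
  data.frame(label = integer(), voxel_count = integer(),
             area_mm2 = numeric(), equivalent_diameter_mm = numeric(),
             centroid_row = numeric(), centroid_col = numeric(),
             volume_ml = numeric())
}
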