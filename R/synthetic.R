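# Ground-truthed synthetic phantoms: stylised T2W-like basal-ganglia
# slices with planted PVS dots and confounds, so the full pipeline can be
# validated without patient data. The phantom reproduces the intensity
# *ordering* the method relies on -- dark air, mid-intensity tissue, bright
# CSF anchoring the top of the scale, PVS dots peaking at 30-90% of the
# maximum -- not anatomy.

#' Synthetic phantom specification
#'
#' Parameters of a single-slice phantom. Defaults are the package's
#' reference study conditions (see the methods vignette): a 192 x 192
#' slice at 0.47 x 0.47 x 6 mm, tissue background at 15% of `out_max`,
#' a bright CSF-like ventricle structure at 95% occupying > 1% of the
#' slice (anchoring the saturating rescale the way real bright CSF does),
#' PVS dots with Gaussian radial profile peaking uniformly at 30-90% of
#' `out_max` with FWHM/2 radius 0.4-0.8 mm, and additive Gaussian noise
#' with SD 2% of `out_max`.
#'
#' @param shape `(rows, cols)` of the slice.
#' @param spacing `(dx, dy, dz)` mm.
#' @param n_pvs number of planted PVS dots.
#' @param dot_radius_range_mm range of the dot radius (= FWHM/2) in mm.
#' @param dot_peak_fraction_range range of dot peak intensity as a
#'   fraction of `out_max`; the canonical PVS range is `[0.30, 0.90]`.
#' @param background_fraction tissue background as a fraction of `out_max`.
#' @param noise_sd_fraction SD of additive Gaussian noise as a fraction of
#'   `out_max`.
#' @param min_separation_mm minimum pairwise distance between dot centres.
#' @param wmh optional list `(n_blobs, radius_mm, peak_fraction)`: diffuse
#'   low-contrast blobs raising the background (WMH-like confound).
#' @param lacunes optional list `(n, diameter_mm, peak_fraction)`:
#'   sharp-edged bright disks larger than 3 mm (lacune-like confound),
#'   placed inside the ROI.
#' @param csf_fraction intensity of the ventricle anchor as a fraction of
#'   `out_max`.
#' @param out_max intensity ceiling of the phantom.
#' @param seed integer RNG seed; identical specs and seeds give
#'   bit-identical phantoms.
#' @return A list of class `pvs_synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(192, 192),
                           spacing = c(0.47, 0.47, 6),
                           n_pvs = 12,
                           dot_radius_range_mm = c(0.4, 0.8),
                           dot_peak_fraction_range = c(0.30, 0.90),
                           background_fraction = 0.15,
                           noise_sd_fraction = 0.02,
                           min_separation_mm = 4,
                           wmh = NULL,
                           lacunes = NULL,
                           csf_fraction = 0.95,
                           out_max = 255,
                           seed = 1L) {
  if (any(dot_peak_fraction_range < 0) || any(dot_peak_fraction_range > 1) ||
      background_fraction < 0 || background_fraction > 1 ||
      noise_sd_fraction < 0 || noise_sd_fraction > 1 ||
      csf_fraction < 0 || csf_fraction > 1)
    pvs_stop("bad_params", "all intensity fractions must lie in [0, 1]")
  if (n_pvs < 0 || min_separation_mm < 0 || any(dot_radius_range_mm <= 0))
    pvs_stop("bad_params", "counts, separations and radii must be non-negative")
  if (!is.null(lacunes) && lacunes$diameter_mm <= 3)
    pvs_stop("bad_params", "lacune diameter must exceed 3 mm")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_pvs = as.integer(n_pvs),
                 dot_radius_range_mm = dot_radius_range_mm,
                 dot_peak_fraction_range = dot_peak_fraction_range,
                 background_fraction = background_fraction,
                 noise_sd_fraction = noise_sd_fraction,
                 min_separation_mm = min_separation_mm,
                 wmh = wmh, lacunes = lacunes,
                 csf_fraction = csf_fraction, out_max = out_max,
                 seed = as.integer(seed)),
            class = "pvs_synthetic_spec")
}

#' Default bilateral ovoid ROI for a phantom slice
#'
#' Two ellipses lateral of the midline ventricle structure, scaled to the
#' slice: centres at mid-height, 26.5% and 73.5% of the width, semi-axes
#' 20% of the rows and 14.5% of the columns.
#'
#' @param shape `(rows, cols)` of the slice.
#' @return A [make_ovoid_roi] result.
#' @export
default_phantom_roi <- function(shape = c(192, 192)) {
  nr <- shape[1]; nc <- shape[2]
  spec <- roi_spec(slice_index = 1L,
                   left_center = c(round(nr / 2), round(nc * 0.265)),
                   right_center = c(round(nr / 2), round(nc * 0.735)),
                   semi_axes = c(round(nr * 0.20), round(nc * 0.145)))
  make_ovoid_roi(shape, spec)
}

#' Operator flags implied by a phantom spec
#'
#' The characteristics an operator would record for the phantom, so the
#' threshold rules can be exercised end-to-end: scattered PVS and a
#' uniform background unless WMH blobs were requested; few focal lesions
#' unless more than two lacunes.
#'
#' @param spec a [synthetic_spec].
#' @return A [case_characteristics] object.
#' @export
phantom_characteristics <- function(spec) {
  n_lac <- if (is.null(spec$lacunes)) 0L else spec$lacunes$n
  case_characteristics(
    scattered_pvs = TRUE,
    uniform_background = is.null(spec$wmh),
    few_focal_lesions = n_lac <= 2L,
    grouped_pvs = FALSE,
    high_background = !is.null(spec$wmh),
    many_lesions = n_lac > 2L,
    poor_quality = FALSE)
}

# Gaussian radial blob blended towards `peak` over a local patch:
# v' = v + (peak - v) * exp(-d^2 / (2 sigma^2)). Returns updated image.
.add_blob <- function(img, center, sigma_px, peak) {
  nr <- nrow(img); nc <- ncol(img)
  w <- ceiling(4 * sigma_px)
  rows <- max(1, center[1] - w):min(nr, center[1] + w)
  cols <- max(1, center[2] - w):min(nc, center[2] + w)
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, `+`)
  g <- exp(-d2 / (2 * sigma_px^2))
  img[rows, cols] <- img[rows, cols] + (peak - img[rows, cols]) * g
  img
}

#' Generate a ground-truthed phantom slice
#'
#' Builds a single-slice [pvs_volume] containing: a dark border (air), an
#' elliptical brain at `background_fraction * out_max`, a bright midline
#' ventricle structure at `csf_fraction * out_max`, optional lacune disks
#' and WMH blobs, Gaussian-profile PVS dots planted inside the ROI with
#' rejection-sampled centres respecting `min_separation_mm` (at most 1000
#' attempts per dot), and additive Gaussian noise, clipped to
#' `[0, out_max]`.
#'
#' @param spec a [synthetic_spec].
#' @param roi a [make_ovoid_roi] result or logical matrix; defaults to
#'   [default_phantom_roi] of the spec's shape.
#' @return A list of class `pvs_phantom` with `volume` (single-slice
#'   [pvs_volume]), `truth` (dot centres, dot and confound label images,
#'   `n_pvs_true`), `roi` and `spec`.
#' @examples
#' ph <- generate_phantom(synthetic_spec(n_pvs = 5, seed = 7))
#' ph$truth$n_pvs_true
#' @export
generate_phantom <- function(spec, roi = NULL) {
  stopifnot(inherits(spec, "pvs_synthetic_spec"))
  if (is.null(roi)) roi <- default_phantom_roi(spec$shape)
  roi_mask <- as_roi_mask(roi)
  if (!all(dim(roi_mask) == spec$shape))
    pvs_stop("shape_mismatch", "ROI shape differs from phantom shape")

  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
  })
  set.seed(spec$seed)

  nr <- spec$shape[1]; nc <- spec$shape[2]
  dx <- spec$spacing[1]
  om <- spec$out_max
  img <- matrix(0, nr, nc)

  # brain ellipse on an air background
  brain <- .ellipse_mask(c(nr, nc), c((nr + 1) / 2, (nc + 1) / 2),
                         c(0.44 * nr, 0.44 * nc), 0)
  img[brain] <- spec$background_fraction * om

  # midline ventricle bars: the bright CSF anchor for the rescale ceiling
  vr <- round(nr * 0.25):round(nr * 0.75)
  half <- round(nc / 2)
  vcols <- c((half - 7):(half - 1), (half + 1):(half + 7))
  img[vr, vcols] <- spec$csf_fraction * om

  confound_masks <- matrix(0L, nr, nc)
  confound_label <- 0L
  lac_centers <- NULL
  lac_excl_mm <- 0

  roi_idx <- which(roi_mask)
  sample_roi_pixel <- function() {
    i <- roi_idx[sample.int(length(roi_idx), 1L)]
    c((i - 1L) %% nr + 1L, (i - 1L) %/% nr + 1L)
  }

  # lacune confounds: sharp bright disks > 3 mm placed wholly inside the ROI
  if (!is.null(spec$lacunes) && spec$lacunes$n > 0) {
    r_px <- spec$lacunes$diameter_mm / 2 / dx
    lac_excl_mm <- spec$lacunes$diameter_mm / 2 + 2
    for (l in seq_len(spec$lacunes$n)) {
      placed <- FALSE
      for (att in seq_len(1000L)) {
        ctr <- sample_roi_pixel()
        rows <- max(1, ctr[1] - ceiling(r_px)):min(nr, ctr[1] + ceiling(r_px))
        cols <- max(1, ctr[2] - ceiling(r_px)):min(nc, ctr[2] + ceiling(r_px))
        d2 <- outer((rows - ctr[1])^2, (cols - ctr[2])^2, `+`)
        disk <- d2 <= r_px^2
        inside <- all(roi_mask[rows, cols][disk])
        far <- is.null(lac_centers) ||
          all(sqrt(rowSums((t(t(lac_centers) - ctr))^2)) * dx >
                spec$lacunes$diameter_mm)
        if (inside && far) {
          confound_label <- confound_label + 1L
          sub <- img[rows, cols]
          sub[disk] <- spec$lacunes$peak_fraction * om
          img[rows, cols] <- sub
          subm <- confound_masks[rows, cols]
          subm[disk] <- confound_label
          confound_masks[rows, cols] <- subm
          lac_centers <- rbind(lac_centers, ctr)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        pvs_stop("placement_infeasible", "could not place a lacune after 1000 attempts")
    }
  }

  # WMH-like diffuse blobs anywhere in the brain
  if (!is.null(spec$wmh) && spec$wmh$n_blobs > 0) {
    brain_idx <- which(brain)
    for (b in seq_len(spec$wmh$n_blobs)) {
      i <- brain_idx[sample.int(length(brain_idx), 1L)]
      ctr <- c((i - 1L) %% nr + 1L, (i - 1L) %/% nr + 1L)
      sigma_px <- (2 * spec$wmh$radius_mm / 2.355) / dx
      img <- .add_blob(img, ctr, sigma_px, spec$wmh$peak_fraction * om)
      confound_label <- confound_label + 1L
      # label the blob core (within its radius)
      rows <- max(1, ctr[1] - ceiling(spec$wmh$radius_mm / dx)):min(nr, ctr[1] + ceiling(spec$wmh$radius_mm / dx))
      cols <- max(1, ctr[2] - ceiling(spec$wmh$radius_mm / dx)):min(nc, ctr[2] + ceiling(spec$wmh$radius_mm / dx))
      d2 <- outer((rows - ctr[1])^2, (cols - ctr[2])^2, `+`)
      subm <- confound_masks[rows, cols]
      core <- d2 <= (spec$wmh$radius_mm / dx)^2 & subm == 0L
      subm[core] <- confound_label
      confound_masks[rows, cols] <- subm
    }
  }

  # PVS dots: rejection-sampled centres, Gaussian radial profile
  dot_centers <- matrix(0L, 0, 2, dimnames = list(NULL, c("row", "col")))
  dot_masks <- matrix(0L, nr, nc)
  if (spec$n_pvs > 0) {
    for (i in seq_len(spec$n_pvs)) {
      placed <- FALSE
      for (att in seq_len(1000L)) {
        ctr <- sample_roi_pixel()
        ok_dots <- nrow(dot_centers) == 0L ||
          all(sqrt(rowSums((t(t(dot_centers) - ctr))^2)) * dx >=
                spec$min_separation_mm)
        ok_lac <- is.null(lac_centers) ||
          all(sqrt(rowSums((t(t(lac_centers) - ctr))^2)) * dx >= lac_excl_mm)
        if (ok_dots && ok_lac) {
          dot_centers <- rbind(dot_centers, ctr)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        pvs_stop("placement_infeasible",
                 sprintf("could not place dot %d of %d after 1000 attempts",
                         i, spec$n_pvs))
    }
    peaks <- stats::runif(spec$n_pvs, spec$dot_peak_fraction_range[1],
                          spec$dot_peak_fraction_range[2]) * om
    radii <- stats::runif(spec$n_pvs, spec$dot_radius_range_mm[1],
                          spec$dot_radius_range_mm[2])
    for (i in seq_len(spec$n_pvs)) {
      sigma_px <- (2 * radii[i] / 2.355) / dx   # FWHM = 2 * radius
      img <- .add_blob(img, dot_centers[i, ], sigma_px, peaks[i])
      r_px <- radii[i] / dx
      rows <- max(1, dot_centers[i, 1] - ceiling(r_px)):min(nr, dot_centers[i, 1] + ceiling(r_px))
      cols <- max(1, dot_centers[i, 2] - ceiling(r_px)):min(nc, dot_centers[i, 2] + ceiling(r_px))
      d2 <- outer((rows - dot_centers[i, 1])^2, (cols - dot_centers[i, 2])^2, `+`)
      subm <- dot_masks[rows, cols]
      subm[d2 <= r_px^2] <- i
      dot_masks[rows, cols] <- subm
    }
  }

  if (spec$noise_sd_fraction > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd_fraction * om), nr, nc)
  img <- pmin(pmax(img, 0), om)

  volume <- pvs_volume(array(img, c(nr, nc, 1L)), spacing = spec$spacing,
                       id = sprintf("phantom-seed%d", spec$seed))
  truth <- structure(list(dot_centers = dot_centers,
                          dot_masks = dot_masks,
                          confound_masks = confound_masks,
                          n_pvs_true = nrow(dot_centers),
                          characteristics = phantom_characteristics(spec)),
                     class = "pvs_ground_truth")
  structure(list(volume = volume, truth = truth, roi = roi, spec = spec),
            class = "pvs_phantom")
}

#' Match detections against planted ground truth
#'
#' Greedy one-to-one matching of detected object centroids to true dot
#' centres: detections are visited in label order and matched to the
#' nearest unmatched true centre within `tolerance_mm`. Matched pairs are
#' true positives; unmatched detections are false positives; unmatched
#' true centres are false negatives, so `TP + FN = n_pvs_true`.
#'
#' @param result a [pvs_segment] result.
#' @param truth the `truth` element of a [generate_phantom] result.
#' @param tolerance_mm maximum centre-to-centroid distance for a match.
#' @return A list with `true_positives`, `false_positives`,
#'   `false_negatives` and the matched index pairs.
#' @export
truth_match <- function(result, truth, tolerance_mm = 2) {
  stopifnot(inherits(result, "pvs_segmentation"),
            inherits(truth, "pvs_ground_truth"))
  dx <- result$spacing[1]; dy <- result$spacing[2]
  n_true <- truth$n_pvs_true
  n_det <- result$count
  matched_true <- logical(n_true)
  pairs <- NULL
  if (n_det > 0 && n_true > 0) {
    for (i in seq_len(n_det)) {
      dr <- (result$objects$centroid_row[i] - truth$dot_centers[, 1]) * dx
      dc <- (result$objects$centroid_col[i] - truth$dot_centers[, 2]) * dy
      d <- sqrt(dr^2 + dc^2)
      d[matched_true] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= tolerance_mm) {
        matched_true[j] <- TRUE
        pairs <- rbind(pairs, c(detected = i, true = j))
      }
    }
  }
  tp <- sum(matched_true)
  list(true_positives = tp,
       false_positives = n_det - tp,
       false_negatives = n_true - tp,
       pairs = pairs)
}
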