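# The three-stage intensity adjustment that precedes thresholding:
# (1) saturating linear rescale to [0, out_max], (2) power-law (gamma)
# correction, (3) quadratic self-combination, equivalent to gamma = 2 on a
# zero-minimum image. PVS peaks span roughly 30-90% of the slice maximum,
# so the quadratic map stretches the bright tail and compresses the tissue
# background, letting a single threshold separate the two.

# Accept a pvs_volume, matrix or array; apply f to the numbers; rewrap.
.map_intensities <- function(x, f) {
  if (inherits(x, "pvs_volume")) {
    out <- x
    out$data <- array(f(x$data), dim(x$data))
    out
  } else if (is.matrix(x)) {
    matrix(f(x), nrow = nrow(x))
  } else {
    array(f(x), dim(x) %||% length(x))
  }
}

.intensity_values <- function(x) {
  if (inherits(x, "pvs_volume")) as.numeric(x$data) else as.numeric(x)
}

#' Adjustment parameters
#'
#' @param saturation_fraction fraction of the lowest and of the highest
#'   intensities saturated at the output extremes; in `[0, 0.5)`.
#'   Default 0.01 (1%).
#' @param gamma exponent of the power-law correction stage; the rescale
#'   stage itself is linear (`gamma = 1`).
#' @param out_max output ceiling of the normalised scale. All threshold
#'   fractions are interpreted relative to `out_max`. Default 255.
#' @return A list of class `pvs_adjust_params`.
#' @export
adjust_params <- function(saturation_fraction = 0.01, gamma = 1, out_max = 255) {
  if (saturation_fraction < 0 || saturation_fraction >= 0.5)
    pvs_stop("bad_params", "`saturation_fraction` must be in [0, 0.5)")
  if (gamma <= 0 || out_max <= 0)
    pvs_stop("bad_params", "`gamma` and `out_max` must be positive")
  structure(list(saturation_fraction = saturation_fraction,
                 gamma = gamma, out_max = out_max),
            class = "pvs_adjust_params")
}

#' Saturating linear rescale
#'
#' Linear intensity transformation saturating a fraction of the lowest and
#' highest intensities at the output extremes. With `n` voxels in the
#' domain and `k = floor(saturation_fraction * n)`, the anchor points are
#' the `(k+1)`-th smallest (`L`) and `(k+1)`-th largest (`H`) intensities;
#' values are clipped to `[L, H]` and mapped affinely onto
#' `[0, out_max]`. The k lowest and k highest voxels are thereby saturated
#' at 0 and `out_max`.
#'
#' @param x a [pvs_volume], matrix (single slice) or array.
#' @param params an [adjust_params] object.
#' @param domain_mask optional logical mask (same shape as `x`) restricting
#'   the voxels from which `L` and `H` are computed; the mapping is still
#'   applied everywhere.
#' @return Same type as `x`, rescaled to `[0, out_max]`.
#' @examples
#' saturate_rescale(matrix(0:199, 10), adjust_params(0.01))
#' @export
saturate_rescale <- function(x, params = adjust_params(), domain_mask = NULL) {
  vals <- .intensity_values(x)
  dom <- if (is.null(domain_mask)) vals else {
    if (length(domain_mask) != length(vals))
      pvs_stop("shape_mismatch", "domain mask shape differs from image")
    v <- vals[as.logical(domain_mask)]
    if (length(v) < 2L) pvs_stop("empty_domain", "domain mask selects < 2 voxels")
    v
  }
  n <- length(dom)
  k <- floor(params$saturation_fraction * n)
  s <- sort(dom)
  L <- s[k + 1L]
  H <- s[n - k]
  if (H <= L)
    pvs_stop("zero_range", "zero dynamic range after saturation")
  .map_intensities(x, function(v) (pmin(pmax(v, L), H) - L) / (H - L) * params$out_max)
}

#' Gamma correction
#'
#' Power-law intensity remapping between the image's own extremes: with
#' `t = (i - I_min) / (I_max - I_min)`, each voxel maps to
#' `i' = (I_max - I_min) * t^gamma + I_min`, so `I_min` and `I_max` are
#' fixed points for every `gamma` and `gamma = 1` is the identity.
#' On a zero-minimum image this is the classical form
#' `I_max * (i / I_max)^gamma`.
#'
#' @param x a [pvs_volume], matrix or array.
#' @param gamma positive exponent; `> 1` darkens the mid-range (stretches
#'   the bright tail), `< 1` brightens it.
#' @return Same type as `x`.
#' @examples
#' gamma_correct(matrix(c(0, 50, 100), 1), gamma = 2) # 0, 25, 100
#' @export
gamma_correct <- function(x, gamma) {
  if (gamma <= 0) pvs_stop("bad_params", "`gamma` must be positive")
  vals <- .intensity_values(x)
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) pvs_stop("zero_range", "zero dynamic range")
  .map_intensities(x, function(v) (hi - lo) * ((v - lo) / (hi - lo))^gamma + lo)
}

#' Quadratic self-combination
#'
#' Voxelwise product of a rescaled image with itself, normalised back onto
#' `[0, out_max]`: `i' = i^2 / out_max`. On an image spanning
#' `[0, out_max]` this equals [gamma_correct()] with `gamma = 2`; it is the
#' combination step applied after the saturating rescale.
#'
#' @param x a [pvs_volume], matrix or array with minimum 0 (i.e. the output
#'   of [saturate_rescale()]).
#' @param out_max the normalisation ceiling used in the rescale stage.
#' @return Same type as `x`, range preserved within `[0, out_max]`.
#' @export
combine_self_product <- function(x, out_max = 255) {
  vals <- .intensity_values(x)
  if (any(vals < 0))
    pvs_stop("negative_intensity", "self-product requires non-negative intensities")
  .map_intensities(x, function(v) v * v / out_max)
}
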