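---
title: "Threshold-based quantification of basal-ganglia perivascular spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based quantification of basal-ganglia perivascular spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsquant)
```

## The problem

Enlarged perivascular spaces (PVS, Virchow-Robin spaces) are fluid-filled
spaces around penetrating vessels, visible on T2-weighted MRI as small
CSF-like hyperintense dots of less than 3 mm cross-section. Their burden in
the basal ganglia (BG) is a marker of cerebral small vessel disease, but
clinical practice rates them on a coarse 0-4 visual scale with known floor
and ceiling effects and observer variability. `pvsquant` implements a
semi-automatic computational alternative: it counts PVS and measures their
volume inside bilateral ovoid BG regions on a single axial T2W slice.

The analysis is deliberately 2D and single-slice: on conventional clinical
T2W (about 0.47 x 0.47 mm in plane, 5 mm slices with a 1 mm gap) through-plane
resolution does not support 3D PVS delineation, and in-plane assessment is
only reliable in the BG ovoids, where the perforating vessels run
transversally through the slice.

## The procedure

For a case, the operator chooses the standard BG slice (the one showing a
characteristic BG structure and the most PVS) and an ROI; the pipeline then
runs:

1. **Saturating rescale.** With $n$ voxels in the adjustment domain and
   $k = \lfloor f \cdot n \rfloor$ ($f$ = `saturation_fraction`, default 1%),
   the anchors $L$ and $H$ are the $(k{+}1)$-th smallest and largest
   intensities; values are clipped to $[L, H]$ and mapped affinely onto
   $[0, I_{max}]$ with $I_{max}$ = `out_max` = 255. The bottom and top $k$
   voxels saturate at the extremes. Order statistics rather than
   interpolated percentiles keep the rule exact and oracle-checkable.
2. **Quadratic self-combination.** The rescaled image is multiplied
   voxelwise with itself and renormalised, $i' = i^2 / I_{max}$. Because
   the rescaled minimum is 0, this equals gamma correction
   $i' = (I_{max}-I_{min})\,t^{\gamma} + I_{min}$,
   $t = (i-I_{min})/(I_{max}-I_{min})$, with $\gamma = 2$. PVS peak at
   roughly 30-90% of the slice maximum; the quadratic map stretches that
   bright tail away from the tissue background so that one threshold can
   separate the two.
3. **Threshold selection.** Three canonical thresholds, as fractions of the
   adjusted maximum: low 7.5%, medium 11.25%, high 15% (or above). The rule:
   *high* whenever the case has grouped PVS, a high background (diffuse
   WMH), many other lesions, or poor scan quality; *low* when it has
   scattered PVS *and* a uniform background *and* few focal lesions;
   *medium* otherwise. Note the quadratic stage means a threshold at
   fraction $q$ of the combined image corresponds to $\sqrt{q}$ on the
   rescaled image: 27.4%, 33.5% and 38.7% for the three levels.
4. **ROI-restricted thresholding.** A pixel is a candidate iff it is inside
   the ROI, not manually excluded, and at or above the threshold (ties
   included -- a deterministic rule that matters for integer phantoms).
5. **Labelling and size filtering.** Candidates are partitioned into
   connected components (8-connectivity by default, since PVS dots at
   0.47 mm pixels can touch diagonally) and filtered by equivalent diameter
   $2\sqrt{A/\pi} \le 3$ mm, which rejects lacune-sized objects and adapts
   to pixel spacing; `min_voxels` (default 1) can suppress single-pixel
   noise. Objects clipped by the ROI boundary are kept with their in-ROI
   area.
6. **Quantification.** Count, and volume as
   `voxel_count * dx * dy * dz / 1000` ml per object. `dz` is the
   centre-to-centre slice spacing (6 mm for 5 mm slices with a 1 mm gap):
   the printed voxel size of the acquisition, adopted over the nominal
   5 mm thickness and configurable through the volume's `spacing`.

Difficult cases re-run with another threshold and/or an exclusion mask over
lesions that mimic PVS (infarcts, mineral deposits); `pvs_segment()` records
the full provenance either way.

## Scores and statistics

`condense_score()` maps counts onto the clinical 0-4 categories with bins
$[0], [1,10], [11,20], [21,39], [40,\infty)$; the published scales print the
boundary counts 10, 20 and 40 ambiguously (each appears in two adjacent
categories), and these half-open bins are the unique monotone
reconciliation. A high-background case scores 4 regardless of count,
mirroring the visual raters' convention. `bland_altman()` reports the mean
and sample (n-1) SD of paired differences with 1.96-SD limits of agreement
(the standard denominators; the method description this package follows does
not state them). `ols_association()` wraps a simple least-squares fit with a
t-based 95% CI and two-sided p on the slope; a perfect fit collapses the CI
and flags the inference degenerate rather than reporting p = 0.

A documented inconsistency in the source material: the development study
reports both 0.11 ml volume increase per PVS dot and 67.3 dots per ml for
the inverse regression, which cannot both hold at the reported median total
volume of about 0.093 ml. The package reproduces the *form* of these
association analyses only; cohort coefficients require the original patient
data.

## The phantom and what it does (not) show

`generate_phantom()` builds a single-slice scene that reproduces the
intensity *ordering* the method relies on, not anatomy:

- a dark border (air) and an elliptical brain at
  `background_fraction * out_max` (default 0.15);
- a bright midline ventricle structure at `csf_fraction * out_max`
  (default 0.95) occupying over 1% of the slice. This anchor is essential:
  the 1%-saturation ceiling $H$ lands in bright CSF exactly as it does on a
  real T2W slice, so threshold fractions mean the same thing on phantom and
  patient data. Without it, $H$ would collapse into the noise or dot
  distribution and the background itself would cross the threshold;
- PVS dots with Gaussian radial profile (radius = FWHM/2, default
  0.4-0.8 mm -- single-peaked, the simplest shape consistent with
  partial-volume blurring), peaks uniform at 30-90% of `out_max`, centres
  rejection-sampled inside the ROI with 4 mm minimum separation, at most
  1000 attempts per dot (bounded runtime, deterministic failure);
- optional confounds: sharp lacune-like disks larger than 3 mm inside the
  ROI, and diffuse WMH-like blobs that raise the background;
- additive Gaussian noise (default SD 2% of `out_max`) clipped to range.
  Rician noise would differ only at near-zero intensities, immaterial for
  threshold behaviour at these background levels.

Defaults are one fixed set of study conditions: a 192 x 192 slice at
0.47 x 0.47 x 6 mm (half the acquisition matrix of the clinical protocol,
which keeps the validation suites fast while preserving the pixel scale that
the millimetre-based filters see). The recovery suite runs 100 seeded
phantoms with 1-40 dots each, plus a 5 mm lacune, and selects the threshold
through the characteristic rules -- such scattered-PVS, uniform-background
phantoms take the *low* threshold, the same path a clean patient scan takes.
The arithmetic explains why: a 30%-peak dot sits at $0.30^2 \approx 9\%$ of
maximum after the quadratic map, below the medium threshold (11.25%) but
above the low one (7.5%); dot peaks at 30-90% are exactly the regime where a
single fixed threshold fails and the adjustment-plus-rules machinery is
needed.

Passing recovery on these phantoms shows the pipeline arithmetic — rescale
anchoring, threshold fractions, connectivity, size filter, truth matching —
is correct under a favourable, known-truth geometry. It does *not* show
clinical validity: real T2W slices have structured backgrounds, elongated
and coalescing PVS, partial-volume gradations and observer-dependent slice
and ROI choices that no phantom of this kind represents.

## Numerical and design choices

- 1-based voxel indexing (R convention) in pure index space; no affine or
  orientation handling. Geometry converts to mm via `spacing` only.
- Intensities are used as stored; no scanner rescale slopes beyond what the
  file format mandates, so the adjustment pipeline is the only intensity
  transform.
- The saturation window and threshold maximum refer to the analysed slice
  by default (`adjust_domain = "slice"`); the whole-volume alternative is
  available and recorded in provenance. The single-slice default matches
  the single-slice procedure.
- Ellipse ROI membership is decided at pixel centres, unrotated or rotated;
  no anti-aliasing, so masks are binary and exhaustively checkable. No
  default ellipse size is claimed to match any anatomical delineation; for
  patient data a hand-drawn mask file is the intended input.
- Only $\gamma = 1$ (rescale stage) and $\gamma = 2$ (combination stage)
  are wired into the pipeline; `gamma_correct()` accepts any positive
  $\gamma$ for exploration.
- `label_objects()` is a vectorised frontier flood fill written in the
  package; it supports both 4- and 8-connectivity and is verified against
  an independent graph-components oracle in the tests.

## Limitations

Semi-automatic by design: slice choice, ROI placement (on patient data),
characteristic flags and any exclusion editing are operator inputs. BG
only -- the centrum semiovale is out of scope because elongated CS PVS
cannot be assessed reliably this way. No DICOM ingestion, registration,
bias-field correction or 3D analysis.
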