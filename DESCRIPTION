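Package: pvsquant
Title: Semi-Automatic Quantification of Perivascular Spaces on T2-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based quantification of enlarged perivascular spaces
    (Virchow-Robin spaces) in the basal ganglia from conventional T2-weighted
    MRI. Implements a three-stage intensity adjustment (saturating rescale,
    gamma correction, quadratic self-combination), bilateral ovoid
    region-of-interest restriction on a single axial slice, rule-based
    selection among low/medium/high intensity thresholds, connected-component
    labelling with an equivalent-diameter size filter, and count and volume
    quantification. Includes condensation of counts onto the 0-4 clinical
    visual rating scale, Bland-Altman observer-agreement and linear-regression
    association utilities, and a ground-truthed synthetic phantom generator
    for validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    oro.nifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
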