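test_that("threshold selection follows the case-characteristic rules", {
  low_case <- case_characteristics(scattered_pvs = TRUE, uniform_background = TRUE,
                                   few_focal_lesions = TRUE)
  expect_equal(select_threshold(low_case)$level, "low")
  expect_equal(select_threshold(low_case)$fraction_of_max, 0.075)

  for (flag in c("grouped_pvs", "high_background", "many_lesions", "poor_quality")) {
    args <- setNames(list(TRUE), flag)
    pol <- select_threshold(do.call(case_characteristics, args))
    expect_equal(pol$level, "high")
    expect_equal(pol$fraction_of_max, 0.15)
  }
  # high criteria dominate even when low criteria are also met
  both <- case_characteristics(scattered_pvs = TRUE, uniform_background = TRUE,
                               few_focal_lesions = TRUE, poor_quality = TRUE)
  expect_equal(select_threshold(both)$level, "high")

  med <- select_threshold(case_characteristics())
  expect_equal(med$level, "medium")
  expect_equal(med$fraction_of_max, 0.1125)

  expect_equal(threshold_policy("high", 0.2)$fraction_of_max, 0.2)
  expect_error(threshold_policy("high", 0.10), class = "pvs_error_bad_params")
  expect_error(threshold_policy("custom"), class = "pvs_error_bad_params")
})

test_that("thresholding keeps exactly the in-ROI pixels at or above the cut", {
  set.seed(31)
  slice <- matrix(runif(64, 0, 255), 8)
  roi <- matrix(FALSE, 8, 8); roi[2:7, 2:7] <- TRUE
  pol <- threshold_policy("medium")
  got <- apply_threshold(slice, roi, pol)
  expect_identical(got, roi & slice >= 0.1125 * 255)
  # brute-force count on a constructed 8x8 patch
  slice2 <- matrix(0, 8, 8)
  slice2[cbind(c(2, 3, 4, 5, 6), c(2, 3, 4, 5, 6))] <- c(30, 40, 100, 200, 255)
  expect_equal(sum(apply_threshold(slice2, roi, pol)), 5)
  # ties are included: pixel exactly at the threshold survives
  slice3 <- matrix(0.1125 * 255, 8, 8)
  expect_equal(sum(apply_threshold(slice3, roi, pol)), sum(roi))
  # fraction 1 keeps only pixels at out_max
  slice4 <- matrix(c(255, 254), 8, 8)
  expect_equal(sum(apply_threshold(slice4, roi, threshold_policy("custom", 1))),
               sum(roi & slice4 == 255))
  # tiny fraction recovers ROI minus exclusions
  excl <- matrix(FALSE, 8, 8); excl[2, 2] <- TRUE
  slice5 <- matrix(runif(64, 1, 255), 8)
  expect_equal(sum(apply_threshold(slice5, roi, threshold_policy("custom", 1e-9), excl)),
               sum(roi) - 1)
  expect_error(apply_threshold(slice, roi[1:4, ], pol), class = "pvs_error_shape_mismatch")
  expect_error(apply_threshold(slice, matrix(FALSE, 8, 8), pol), class = "pvs_error_empty_mask")
})

test_that("component labelling distinguishes 4- and 8-connectivity", {
  expect_length(label_objects(matrix(FALSE, 5, 5)), 0)
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_length(label_objects(m, 4), 2)
  expect_length(label_objects(m, 8), 1)
  # three disjoint 2x2 squares
  m3 <- matrix(FALSE, 10, 10)
  m3[1:2, 1:2] <- TRUE; m3[5:6, 5:6] <- TRUE; m3[9:10, 1:2] <- TRUE
  comps <- label_objects(m3, 8)
  expect_length(comps, 3)
  expect_equal(vapply(comps, nrow, integer(1)), rep(4L, 3))
})

test_that("labelling matches the graph-components oracle on random masks", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (i in 1:60) {
    mask <- matrix(runif(32 * 32) < runif(1, 0.2, 0.7), 32)
    for (conn in c(4, 8)) {
      got <- canonical_partition(label_objects(mask, conn), 32)
      want <- canonical_partition(oracle_components(mask, conn), 32)
      expect_identical(got, want)
    }
  }
})

test_that("size filtering applies the hand-computed equivalent diameters", {
  px <- function(n) cbind(row = seq_len(n), col = rep(1L, n))
  comps <- list(px(1), px(60), px(7))
  out <- filter_objects(comps, size_filter(), spacing = c(0.47, 0.47, 6))
  # 1 px: d = 2*sqrt(0.2209/pi) = 0.530 mm -> kept; 60 px: 4.108 mm -> removed
  expect_equal(nrow(out), 2)
  expect_equal(out$equivalent_diameter_mm[1], 2 * sqrt(0.2209 / pi), tolerance = 1e-12)
  expect_equal(out$voxel_count, c(1L, 7L))
  expect_equal(out$area_mm2, c(1, 7) * 0.2209)
  # min_voxels 2 removes singletons
  out2 <- filter_objects(comps, size_filter(min_voxels = 2), c(0.47, 0.47, 6))
  expect_equal(out2$voxel_count, 7L)
  # identity filter keeps everything
  out3 <- filter_objects(comps, size_filter(1, Inf), c(0.47, 0.47, 6))
  expect_equal(nrow(out3), 3)
})

test_that("quantification converts pixel counts to millilitres linearly in dz", {
  comps <- lapply(1:10, function(i) cbind(row = i * 3 + 1:7, col = rep(1L, 7)))
  sp <- c(0.47, 0.47, 6)
  obj <- filter_objects(comps, size_filter(), sp)
  q <- quantify(obj, sp)
  expect_equal(q$count, 10)
  expect_equal(q$total_volume_ml, 70 * 1.3254 / 1000)  # 0.092778 ml
  obj2 <- filter_objects(comps, size_filter(), c(0.47, 0.47, 12))
  expect_equal(quantify(obj2, sp)$total_volume_ml, 2 * q$total_volume_ml)
  expect_equal(quantify(empty_object_table(), sp)$count, 0)
  expect_equal(quantify(empty_object_table(), sp)$total_volume_ml, 0)
})

test_that("the full pipeline recovers planted dots and honours the exclusion mask", {
  spec <- synthetic_spec(n_pvs = 12, dot_peak_fraction_range = c(0.45, 0.90), seed = 303)
  ph <- generate_phantom(spec)
  res <- pvs_segment(ph$volume, 1, ph$roi, policy = threshold_policy("medium"))
  expect_equal(res$count, 12)
  expect_equal(res$total_volume_ml, sum(res$objects$volume_ml))

  # exclusion mask over one planted dot removes exactly that detection
  excl <- matrix(FALSE, 192, 192)
  ctr <- ph$truth$dot_centers[1, ]
  excl[ctr[1] + (-4:4), ctr[2] + (-4:4)] <- TRUE
  res_excl <- pvs_segment(ph$volume, 1, ph$roi, policy = threshold_policy("medium"),
                          exclusion_mask = excl)
  expect_equal(res_excl$count, 11)
  expect_true(res_excl$provenance$exclusion_mask_used)

  expect_error(pvs_segment(ph$volume, 1, matrix(FALSE, 192, 192),
                           policy = threshold_policy("medium")),
               class = "pvs_error_empty_mask")
  expect_error(pvs_segment(ph$volume, 1, ph$roi), class = "pvs_error_bad_params")
})

test_that("count and volume are invariant under translation of slice, ROI and exclusions", {
  spec <- synthetic_spec(n_pvs = 8, dot_peak_fraction_range = c(0.45, 0.9), seed = 99)
  ph <- generate_phantom(spec)
  res <- pvs_segment(ph$volume, 1, ph$roi, policy = threshold_policy("medium"))
  # translate the whole scene by (3, -2)
  sh <- function(m, dr, dc, fill = 0) {
    out <- matrix(fill, nrow(m), ncol(m))
    out[(1 + max(0, dr)):(nrow(m) + min(0, dr)),
        (1 + max(0, dc)):(ncol(m) + min(0, dc))] <-
      m[(1 - min(0, dr)):(nrow(m) - max(0, dr)),
        (1 - min(0, dc)):(ncol(m) - max(0, dc))]
    out
  }
  vol2 <- pvs_volume(array(sh(ph$volume$data[, , 1], 3, -2), c(192, 192, 1)),
                     ph$volume$spacing)
  roi2 <- sh(ph$roi$mask, 3, -2, FALSE) > 0
  res2 <- pvs_segment(vol2, 1, roi2, policy = threshold_policy("medium"))
  expect_equal(res2$count, res$count)
  expect_equal(res2$total_volume_ml, res$total_volume_ml)
})

test_that("candidate masks nest as the threshold rises", {
  set.seed(13)
  roi <- default_phantom_roi()$mask
  for (i in 1:5) {
    ph <- generate_phantom(synthetic_spec(n_pvs = 20, seed = 400 + i))
    adj <- combine_self_product(saturate_rescale(ph$volume$data[, , 1], adjust_params()))
    m_low <- apply_threshold(adj, roi, threshold_policy("low"))
    m_med <- apply_threshold(adj, roi, threshold_policy("medium"))
    m_high <- apply_threshold(adj, roi, threshold_policy("high"))
    expect_true(all(m_high <= m_med))
    expect_true(all(m_med <= m_low))
  }
})

test_that("count is non-increasing in the threshold fraction on single-peaked phantoms", {
  ph <- generate_phantom(synthetic_spec(n_pvs = 25, seed = 555))
  counts <- vapply(c(0.05, 0.075, 0.1125, 0.15, 0.25, 0.5), function(f)
    pvs_segment(ph$volume, 1, ph$roi,
                policy = threshold_policy("custom", f))$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
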