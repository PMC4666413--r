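test_that("phantoms are bit-identical for a fixed seed and leave the RNG state alone", {
  spec <- easy_spec(n_pvs = 9, seed = 42)
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- generate_phantom(spec)
  after <- runif(1)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$dot_centers, b$truth$dot_centers)
  expect_identical(a$truth$confound_masks, b$truth$confound_masks)
  expect_equal(before, after)  # generator restored the caller's RNG stream
})

test_that("a dotless noiseless phantom yields a flat background and count zero", {
  ph <- generate_phantom(synthetic_spec(n_pvs = 0, noise_sd_fraction = 0, seed = 5))
  roi_px <- ph$volume$data[, , 1][ph$roi$mask]
  expect_equal(unique(roi_px), 0.15 * 255)
  res <- pvs_segment(ph$volume, 1, ph$roi, policy = threshold_policy("medium"))
  expect_equal(res$count, 0)
  expect_equal(res$total_volume_ml, 0)
})

test_that("planted dots respect the ROI and the minimum separation", {
  spec <- easy_spec(n_pvs = 30, seed = 17)
  ph <- generate_phantom(spec)
  ctr <- ph$truth$dot_centers
  expect_equal(nrow(ctr), 30)
  expect_true(all(ph$roi$mask[ctr]))
  d <- as.matrix(dist(ctr)) * spec$spacing[1]
  diag(d) <- Inf
  expect_true(all(d >= spec$min_separation_mm))
})

test_that("infeasible placement fails with a named error", {
  tight <- synthetic_spec(n_pvs = 500, min_separation_mm = 6, seed = 2)
  expect_error(generate_phantom(tight), class = "pvs_error_placement_infeasible")
})

test_that("truth matching partitions detections and truths", {
  spec <- easy_spec(n_pvs = 15, seed = 23)
  ph <- generate_phantom(spec)
  res <- pvs_segment(ph$volume, 1, ph$roi,
                     characteristics = ph$truth$characteristics)
  m <- truth_match(res, ph$truth)
  expect_equal(m$true_positives + m$false_negatives, ph$truth$n_pvs_true)
  expect_equal(m$true_positives + m$false_positives, res$count)
  expect_equal(m$false_positives, 0)
  expect_equal(m$false_negatives, 0)
})

test_that("a dot below the threshold contrast is reported as a false negative", {
  # dim dots at 12% of out_max: below even the low threshold pre-squaring cut
  spec <- synthetic_spec(n_pvs = 6, dot_peak_fraction_range = c(0.60, 0.90),
                         noise_sd_fraction = 0.01, seed = 31)
  ph <- generate_phantom(spec)
  dim_spec <- synthetic_spec(n_pvs = 6, dot_peak_fraction_range = c(0.10, 0.12),
                             noise_sd_fraction = 0.01, seed = 31)
  ph_dim <- generate_phantom(dim_spec)
  # same geometry (same seed -> same centres), only peaks differ
  expect_identical(ph$truth$dot_centers, ph_dim$truth$dot_centers)
  res <- pvs_segment(ph_dim$volume, 1, ph_dim$roi, policy = threshold_policy("low"))
  m <- truth_match(res, ph_dim$truth)
  expect_equal(m$true_positives, 0)
  expect_equal(m$false_negatives, 6)
})

test_that("WMH-like blobs raise the background and trip the high-threshold rule", {
  spec <- synthetic_spec(n_pvs = 10,
                         wmh = list(n_blobs = 6, radius_mm = 8, peak_fraction = 0.45),
                         seed = 61)
  chars <- phantom_characteristics(spec)
  expect_true(chars$high_background)
  expect_equal(select_threshold(chars)$level, "high")
  ph <- generate_phantom(spec)
  # background inside the ROI is brighter than in the WMH-free phantom
  clean <- generate_phantom(easy_spec(n_pvs = 10, seed = 61))
  roi <- ph$roi$mask & ph$truth$dot_masks == 0 & ph$truth$confound_masks == 0
  expect_gt(median(ph$volume$data[, , 1][roi]),
            median(clean$volume$data[, , 1][clean$roi$mask]))
})
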