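test_that("peak detection handles flat traces and locates apexes precisely", {
  flat <- simulate_trace(data.frame(size_bp = numeric(0),
                                    amount = numeric(0)),
                         fix_model(noise_sd_fu = 0, marker_height_fu = 0),
                         1)
  expect_equal(nrow(detect_peaks(flat)), 0)

  model <- fix_model(noise_sd_fu = 0)
  tr <- simulate_trace(data.frame(size_bp = 160, amount = 1), model, 1)
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 3)
  expect_lt(abs(pk$time_s[2] - (model$t0 + model$slope * log10(160))),
            model$dt_s)
  expect_true(all(pk$height_fu > 0))
  expect_true(all(pk$area > 0))
})

test_that("detection threshold scales with the noise estimate", {
  model <- fix_model(noise_sd_fu = 1, amount_scale_fu = 5,
                     marker_height_fu = 60)
  # fragment peak of height 5 x noise sd between the tall markers
  tr <- simulate_trace(data.frame(size_bp = 300, amount = 1), model, 3)
  t300 <- model$t0 + model$slope * log10(300)
  near <- function(pk) any(abs(pk$time_s - t300) < 0.1)
  expect_false(near(detect_peaks(tr, min_snr = 10)))
  expect_true(near(detect_peaks(tr, min_snr = 3)))
})

test_that("ladder calibration passes through the rungs and is monotone", {
  panel <- fix_panel()
  model <- fix_model(noise_sd_fu = 0)
  lad <- simulate_ladder_trace(panel, model, 1)
  cal <- fit_calibration(lad, panel$ladder_sizes_bp)
  # interpolation is exact at the anchors
  expect_equal(time_to_size(cal, cal$anchor_time_s), panel$ladder_sizes_bp,
               tolerance = 1e-9)
  # and inverts the known log-linear migration law within 0.5 bp at rungs
  true_t <- model$t0 + model$slope * log10(panel$ladder_sizes_bp)
  expect_lt(max(abs(time_to_size(cal, true_t) - panel$ladder_sizes_bp)), 0.5)
  grid <- seq(min(cal$anchor_time_s), max(cal$anchor_time_s),
              length.out = 1000)
  expect_false(is.unsorted(time_to_size(cal, grid), strictly = TRUE))
})

test_that("rung/peak count mismatch aborts calibration with both counts", {
  panel <- fix_panel()
  model <- fix_model(noise_sd_fu = 0)
  # ladder missing the 300 bp rung: 10 peaks detected vs 11 rungs expected
  short <- simulate_trace(
    data.frame(size_bp = setdiff(panel$ladder_sizes_bp, 300), amount = 1),
    model, 1, well_kind = "ladder")
  expect_error(fit_calibration(short, panel$ladder_sizes_bp), "10.*11")
})

test_that("internal-marker alignment recovers affine time distortion", {
  panel <- fix_panel()
  model <- fix_model()
  cal <- fix_calibration(panel, model, seed = 1)
  tr <- simulate_sample_trace(panel, 3, hoxb8_profiles()[[1]], model, 5)
  aligned <- align_internal_markers(tr, cal)
  expect_equal(attr(aligned, "align_scale"), 1, tolerance = 1e-3)
  expect_equal(attr(aligned, "align_shift"), 0, tolerance = 0.2)
  # +5 s drift of the whole well is undone exactly
  drifted <- tr
  drifted$time_s <- tr$time_s + 5
  re <- align_internal_markers(drifted, cal)
  expect_equal(attr(re, "align_shift"),
               attr(aligned, "align_shift") - 5 * attr(re, "align_scale"),
               tolerance = 1e-6)
  expect_equal(re$time_s, aligned$time_s, tolerance = 1e-6)
  # markers undetectable -> alignment error
  flat <- simulate_trace(data.frame(size_bp = numeric(0),
                                    amount = numeric(0)),
                         fix_model(noise_sd_fu = 0, marker_height_fu = 0), 1)
  expect_error(align_internal_markers(flat, cal), "marker")
})

test_that("fragments are sized within the chip's 5 bp resolution", {
  panel <- fix_panel()
  model <- fix_model()
  cal <- fix_calibration(panel, model, seed = 1)
  tr <- simulate_trace(data.frame(size_bp = 160, amount = 1), model, 2,
                       lower_marker_bp = panel$lower_marker_bp,
                       upper_marker_bp = panel$upper_marker_bp)
  sp <- size_peaks(tr, cal)
  expect_equal(nrow(sp), 1)  # markers excluded from the output
  expect_lt(abs(sp$size_bp - 160), 5)
  expect_true(sp$in_sizing_range)

  set.seed(21)
  sizes <- runif(10, 130, 515)
  for (i in seq_along(sizes)) {
    tr <- simulate_trace(data.frame(size_bp = sizes[i], amount = 1), model,
                         30 + i)
    sp <- size_peaks(tr, cal)
    expect_equal(nrow(sp), 1)
    expect_lt(abs(sp$size_bp - sizes[i]), 5)
  }
})

test_that("sizing is invariant to affine time distortion of the sample well", {
  panel <- fix_panel()
  model <- fix_model()
  cal <- fix_calibration(panel, model, seed = 1)
  tr <- simulate_sample_trace(panel, 4, mpdac_profiles()[["mPDAC06"]],
                              model, 9)
  distorted <- tr
  distorted$time_s <- 1.03 * tr$time_s + 2.5
  s0 <- size_peaks(tr, cal)
  s1 <- size_peaks(distorted, cal)
  expect_equal(nrow(s0), nrow(s1))
  expect_lt(max(abs(s0$size_bp - s1$size_bp)), 0.1)
})
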