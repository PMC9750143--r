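test_that("noise-free rendering is deterministic and encodes the imposed sorting", {
  f1 <- generate_tube_frame(imaging_ground_truth(seed = 33))
  f2 <- generate_tube_frame(imaging_ground_truth(seed = 33))
  expect_identical(f1$membrane, f2$membrane)
  expect_identical(f1$protein, f2$protein)

  # S = 1: protein/membrane ratio identical on tube and GUV
  fr <- generate_tube_frame(quiet_gt(sorting_true = 1, seed = 1))
  m <- measure_intensities(fr, segment_rois(fr))
  expect_equal(sorting_ratio(m), 1, tolerance = 1e-9)

  # S = 4: tube protein/membrane ratio is 4x the GUV ratio by construction
  # (tolerance limited by the far PSF tail of the rim under the tube region)
  fr4 <- generate_tube_frame(quiet_gt(sorting_true = 4, seed = 1))
  m4 <- measure_intensities(fr4, segment_rois(fr4))
  expect_equal((m4$I_prot_tube / m4$I_mem_tube) /
                 (m4$I_prot_guv / m4$I_mem_guv), 4, tolerance = 1e-6)
})

test_that("tube membrane signal is proportional to tube radius", {
  # oracle: total unblurred tube signal scales with the membrane area per
  # unit length, i.e. linearly in the radius
  f50 <- generate_tube_frame(quiet_gt(tube_radius_true = 50, psf_sigma = 0,
                                      seed = 2))
  f25 <- generate_tube_frame(quiet_gt(tube_radius_true = 25, psf_sigma = 0,
                                      seed = 2))
  # restrict to tube pixels clear of the rim so the oracle sums pure tube
  # signal (at the junction one pixel carries rim + tube intensity)
  away <- col(f50$membrane) > f50$truth$geometry$x_junction + 10
  mask <- f50$truth$tube_mask_true & !f50$truth$guv_mask_true & away
  s50 <- sum(f50$membrane[mask] - f50$truth$background)
  s25 <- sum(f25$membrane[mask] - f25$truth$background)
  expect_equal(s50 / s25, 2, tolerance = 1e-12)

  # the measured mask-mean ratio matches, unblurred exactly and blurred
  # within a few percent
  r50 <- measure_intensities(f50, segment_rois(f50, psf_sigma = 0))
  r25 <- measure_intensities(f25, segment_rois(f25, psf_sigma = 0))
  expect_equal((r50$I_mem_tube / r50$I_mem_guv) /
                 (r25$I_mem_tube / r25$I_mem_guv), 2, tolerance = 1e-10)
  b50 <- generate_tube_frame(quiet_gt(tube_radius_true = 50, seed = 2))
  b25 <- generate_tube_frame(quiet_gt(tube_radius_true = 25, seed = 2))
  m50 <- measure_intensities(b50, segment_rois(b50))
  m25 <- measure_intensities(b25, segment_rois(b25))
  expect_equal((m50$I_mem_tube / m50$I_mem_guv) /
                 (m25$I_mem_tube / m25$I_mem_guv), 2, tolerance = 0.05)
})

test_that("timecourse generation validates its series and degenerate cases", {
  gts <- replicate(5, quiet_gt(seed = 4), simplify = FALSE)
  frames <- generate_timecourse(gts)
  expect_length(frames, 5)
  S <- vapply(frames, function(f) {
    sorting_ratio(measure_intensities(f, segment_rois(f)))
  }, 0)
  expect_lt(sd(S) / mean(S), 0.05)  # constant ground truth -> flat course

  expect_length(generate_timecourse(gts[1]), 1)
  expect_error(generate_timecourse(list()), "empty")
  decreasing <- list(quiet_gt(sorting_true = 10), quiet_gt(sorting_true = 5))
  expect_error(generate_timecourse(decreasing), "monotone")
})

test_that("ground-truth validation rejects impossible geometry", {
  expect_error(imaging_ground_truth(tube_radius_true = -5))
  expect_error(imaging_ground_truth(sorting_true = -1))
  # tube radius comparable to the GUV radius violates the thin-tube limit
  expect_error(imaging_ground_truth(tube_radius_true = 500, guv_radius_true = 8),
               "smaller")
  # GUV too large for the frame: no room for a tube
  expect_error(generate_tube_frame(imaging_ground_truth(guv_radius_true = 14)),
               "extent")
})
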