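test_that("sorting ratio follows the ratio-of-ratios definition", {
  m <- list(I_prot_tube = 200, I_mem_tube = 100, I_prot_guv = 50,
            I_mem_guv = 100)
  expect_equal(sorting_ratio(m), 4)
  expect_equal(sorting_ratio(list(I_prot_tube = 30, I_mem_tube = 60,
                                  I_prot_guv = 15, I_mem_guv = 30)), 1)
  expect_equal(sorting_ratio(list(I_prot_tube = 0, I_mem_tube = 100,
                                  I_prot_guv = 50, I_mem_guv = 100)), 0)
  expect_warning(
    out <- sorting_ratio(list(I_prot_tube = 10, I_mem_tube = 0,
                              I_prot_guv = 50, I_mem_guv = 100)),
    "denominator")
  expect_true(is.na(out))
})

test_that("fluorescence radius scales the membrane intensity ratio by k_tub", {
  expect_equal(tube_radius_from_fluorescence(1, 200), 200)
  expect_equal(tube_radius_from_fluorescence(0.25, 200), 50)
  m <- list(I_mem_tube = 25, I_mem_guv = 100)
  expect_equal(tube_radius_from_fluorescence(m, 200), 50)
  expect_error(tube_radius_from_fluorescence(-0.1, 200), "positive")
})

test_that("aspiration tension obeys the Laplace relation", {
  expect_equal(membrane_tension(0, 2, 10), 0)
  # independent oracle: invert dP = 2 sigma (1/r_pip - 1/r_guv)
  dP <- 100; r_pip <- 2e-6; r_guv <- 10e-6
  sigma_expected <- dP / (2 * (1 / r_pip - 1 / r_guv))
  expect_equal(membrane_tension(100, 2, 10), sigma_expected, tolerance = 1e-12)
  expect_equal(membrane_tension(200, 2, 10), 2 * membrane_tension(100, 2, 10))
  expect_error(membrane_tension(100, 10, 10), "geometry")
  expect_error(membrane_tension(-5, 2, 10), "non-negative")
})

test_that("tether radius from force is dimensionally consistent", {
  expect_equal(radius_from_force(0, 8e-5), 0)
  expect_equal(radius_from_force(10, 8e-5), 9.947184, tolerance = 1e-6)
  expect_equal(radius_from_force(10, 16e-5), radius_from_force(10, 8e-5) / 2)
  # F = 4 pi sigma * (1 nm) must give R = 1 nm exactly
  sigma <- 3.3e-5
  expect_equal(radius_from_force(4 * pi * sigma * 1e3, sigma), 1,
               tolerance = 1e-12)
  expect_error(radius_from_force(10, 0), "positive")
})

test_that("tension -> force -> regression round trip is exact", {
  for (s in 1:5) {
    k <- runif(1, 100, 300)
    cal <- generate_calibration_pulls(15, k_tub_true = k, noise = 0, seed = s)
    expect_equal(fit_ktub(cal)$k_tub, k, tolerance = 1e-9)
  }
  one_ratio <- generate_calibration_pulls(5, 200, noise = 0, seed = 1)
  one_ratio$ratio <- rep(0.5, 5)
  expect_error(fit_ktub(one_ratio), "distinct")
})

test_that("surface density calibration converts intensity to density", {
  expect_equal(reference_label_density(0.003), 2 * 0.003 / 0.7 * 1e6)
  cal <- density_calibration(1.2, 0.7, 0.26)
  expect_equal(surface_density(0, cal), 0)
  expect_equal(surface_density(100, cal), 100 / 0.26 * 0.7 / 1.2)
  expect_equal(surface_density(100, cal, copies_per_complex = 2),
               surface_density(100, cal) / 2)
  expect_error(surface_density(100, list(a = 1)), "calibration")
})

test_that("density round-trips through rendered standards", {
  # noise-free standards and frame: the optical geometry cancels exactly
  std <- generate_density_standards(base_gt = quiet_gt(), seed = 5)
  fr <- generate_tube_frame(quiet_gt(density_guv_true = 1000, seed = 9))
  m <- measure_intensities(fr, segment_rois(fr))
  phi <- surface_density(m$I_prot_guv, std$calibration)
  expect_lt(abs(phi / 1000 - 1), 1e-6)
})

test_that("timecourse analysis reports endpoints, slope and degeneracies", {
  flat <- data.frame(t = 0:5, phi_tube = rep(800, 6), R_nm = rep(40, 6))
  rec <- timecourse_analysis(flat)
  expect_true("flat" %in% rec$flags)
  expect_true(is.na(rec$slope))

  ramp_phi <- data.frame(t = 0:5, phi_tube = seq(600, 1100, 100),
                         R_nm = rep(40, 6))
  rec2 <- timecourse_analysis(ramp_phi, window = 2)
  expect_true("infinite_slope" %in% rec2$flags)
  expect_equal(rec2$phi_initial, 650)
  expect_equal(rec2$phi_final, 1050)

  both <- data.frame(t = 0:9, phi_tube = seq(600, 1700, length.out = 10),
                     R_nm = seq(50, 25, length.out = 10))
  rec3 <- timecourse_analysis(both)
  expect_lt(rec3$slope, 0)
  expect_equal(rec3$slope, (1700 - 600) / (25 - 50), tolerance = 1e-9)

  expect_error(timecourse_analysis(both[1, ]), "at least 2")
})
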