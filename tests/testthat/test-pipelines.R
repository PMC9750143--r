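test_that("pipeline configuration round-trips losslessly through YAML", {
  cfg <- pipeline_config(frames_dir = "frames", output_dir = "out",
                         k_tub = 213.77,
                         density_cal = list(slope_protein_fluor = 1.2,
                                            slope_lipid_fluor = 0.7,
                                            guv_intensity_vs_density = 0.2597725),
                         seed = 42L)
  path <- file.path(withr::local_tempdir(), "cfg.yaml")
  write_pipeline_config(cfg, path)
  cfg2 <- read_pipeline_config(path)
  expect_identical(unclass(cfg)[sort(names(cfg))],
                   unclass(cfg2)[sort(names(cfg2))])
  expect_error(pipeline_config(k_tub = -1))
})

test_that("sorting pipeline recovers an imposed linear sorting-curvature law", {
  radii <- c(25, 30, 40, 50, 60, 80, 100, 120)
  gts <- lapply(seq_along(radii), function(i) {
    imaging_ground_truth(
      tube_radius_true = radii[i], sorting_true = 1 + 400 / radii[i],
      density_guv_true = if (i %% 2) 100 else 400, seed = 100 + i)
  })
  frames <- lapply(gts, generate_tube_frame)
  std <- generate_density_standards(seed = 5)
  outdir <- withr::local_tempdir()
  cfg <- pipeline_config(
    output_dir = outdir,
    density_cal = std$calibration[c("slope_protein_fluor", "slope_lipid_fluor",
                                    "guv_intensity_vs_density")],
    seed = 42)
  out <- run_sorting_pipeline(cfg, frames = frames)
  expect_setequal(out$fits$group, c("high", "low"))
  for (g in c("high", "low")) {
    expect_equal(out$fits$slope[out$fits$group == g], 400, tolerance = 0.1)
    expect_equal(out$fits$intercept[out$fits$group == g], 1, tolerance = 0.25)
  }
  expect_true(all(c("sorting_results.csv", "sorting_fits.csv",
                    "sorting_vs_curvature.png") %in% list.files(outdir)))
  expect_true(all(out$results$config_hash == out$config_hash))

  # identical config and seed give byte-identical result tables
  outdir2 <- withr::local_tempdir()
  cfg2 <- cfg; cfg2$output_dir <- outdir2
  run_sorting_pipeline(cfg2, frames = frames)
  expect_identical(
    readLines(file.path(outdir, "sorting_results.csv")),
    readLines(file.path(outdir2, "sorting_results.csv")))

  expect_error(run_sorting_pipeline(cfg, frames = list()), "empty|no valid")
})

test_that("flat cohorts give a flat sorting-curvature fit", {
  frames <- lapply(c(30, 50, 80, 110), function(R) {
    generate_tube_frame(quiet_gt(tube_radius_true = R, sorting_true = 1,
                                 seed = R))
  })
  out <- run_sorting_pipeline(pipeline_config(seed = 1), frames = frames)
  fit <- out$fits[out$fits$group == "all", ]
  expect_lt(abs(fit$intercept - 1), 0.05)
  expect_lt(abs(fit$slope), 2)  # |S(1/R) slope| small vs the imposed-law scale
})

test_that("curvature pipeline produces gated histograms and insertion depth", {
  traj <- generate_buckled_membrane(
    buckle_ground_truth(n_frames = 40, lipid_count = 1600, seed = 3))
  path <- file.path(withr::local_tempdir(), "traj.csv")
  write_buckle_csv(traj, path)
  outdir <- withr::local_tempdir()
  cfg <- pipeline_config(trajectory_file = path, output_dir = outdir,
                         insertion_radius = 2.5, seed = 7)
  out <- run_curvature_pipeline(cfg)
  expect_gt(out$summary$mean_H_probe, out$summary$mean_H_random)
  expect_equal(out$summary$n_frames, 36)
  expect_true(all(c("curvature_histogram.csv", "curvature_summary.csv",
                    "curvature_histogram.png") %in% list.files(outdir)))

  cfg_bad <- pipeline_config(trajectory_file = "does-not-exist.csv", seed = 1)
  expect_error(run_curvature_pipeline(cfg_bad), "not found")
  expect_error(run_curvature_pipeline(pipeline_config(seed = 1)),
               "no input trajectory")
})
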