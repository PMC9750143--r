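test_that("the Fourier basis reproduces an exact sinusoid to machine precision", {
  set.seed(1)
  Lx <- 63; Ly <- 28; A <- 3
  x <- runif(800, 0, Lx); y <- runif(800, 0, Ly)
  z <- A * sin(2 * pi * x / Lx)
  s <- fit_membrane_profile(data.frame(x = x, y = y, z = z), c(Lx, Ly),
                            orders = c(2, 1))
  expect_lt(s$rms, 1e-10)
  gx <- seq(0, Lx, length.out = 40); gy <- rep(10, 40)
  expect_equal(membrane_height(s, gx, gy), A * sin(2 * pi * gx / Lx),
               tolerance = 1e-10)
})

test_that("flat sheets give zero curvature and jitter-limited residuals", {
  set.seed(2)
  x <- runif(1500, 0, 63); y <- runif(1500, 0, 28)
  exact <- fit_membrane_profile(data.frame(x = x, y = y, z = rep(2, 1500)),
                                c(63, 28))
  expect_lt(max(abs(mean_curvature(exact, runif(100, 0, 63),
                                   runif(100, 0, 28)))), 1e-10)
  jit <- fit_membrane_profile(
    data.frame(x = x, y = y, z = 2 + rnorm(1500, 0, 0.3)), c(63, 28))
  expect_equal(jit$rms, 0.3, tolerance = 0.2)
  # all non-constant coefficients drowned in jitter, none significant
  expect_lt(max(abs(jit$coef[-1])), 5 * 0.3 / sqrt(1500 / 2))
})

test_that("crest curvature matches the closed form and the FD oracle", {
  set.seed(3)
  Lx <- 63; Ly <- 28; A <- 6
  x <- runif(4000, 0, Lx); y <- runif(4000, 0, Ly)
  # exact sinusoid: any truncation error of the default order shows up here
  s <- fit_membrane_profile(
    data.frame(x = x, y = y, z = A * sin(2 * pi * x / Lx)), c(Lx, Ly))
  H_crest <- mean_curvature(s, Lx / 4, Ly / 2)
  expect_gt(H_crest, 0)  # crest bulges toward the binding side
  expect_equal(abs(H_crest), 2 * pi^2 * A / Lx^2, tolerance = 0.02)
  expect_lt(mean_curvature(s, 3 * Lx / 4, Ly / 2), 0)

  # analytic-derivative curvature against the finite-difference shape
  # operator, on a jittered fit so mixed terms are exercised
  sj <- fit_membrane_profile(
    data.frame(x = x, y = y,
               z = A * sin(2 * pi * x / Lx) + rnorm(4000, 0, 0.3)),
    c(Lx, Ly))
  xs <- runif(1000, 0, Lx); ys <- runif(1000, 0, Ly)
  expect_lt(max(abs(mean_curvature(sj, xs, ys) -
                      fd_mean_curvature(sj, xs, ys))), 1e-4)
})

test_that("jittered sine sheets are recovered to jitter-limited accuracy", {
  set.seed(31)
  Lx <- 63; Ly <- 28; A <- 3; n <- 4000; jit <- 0.3
  x <- runif(n, 0, Lx); y <- runif(n, 0, Ly)
  z <- A * sin(2 * pi * x / Lx) + rnorm(n, 0, jit)
  s <- fit_membrane_profile(data.frame(x = x, y = y, z = z), c(Lx, Ly))
  gx <- runif(300, 0, Lx); gy <- runif(300, 0, Ly)
  err <- membrane_height(s, gx, gy) - A * sin(2 * pi * gx / Lx)
  # coefficient noise scale: jit * sqrt(n_basis / n)
  expect_lt(max(abs(err)), 6 * jit * sqrt(65 / n))
})

test_that("mean curvature is invariant to origin shifts and height offsets", {
  set.seed(4)
  Lx <- 63; Ly <- 28
  x <- runif(2000, 0, Lx); y <- runif(2000, 0, Ly)
  z <- 4 * sin(2 * pi * x / Lx) + 0.5 * cos(2 * pi * y / Ly)
  s0 <- fit_membrane_profile(data.frame(x = x, y = y, z = z), c(Lx, Ly))
  # add a constant to the height field
  s1 <- fit_membrane_profile(data.frame(x = x, y = y, z = z + 7), c(Lx, Ly))
  qx <- runif(50, 0, Lx); qy <- runif(50, 0, Ly)
  expect_equal(mean_curvature(s1, qx, qy), mean_curvature(s0, qx, qy),
               tolerance = 1e-8)
  # translate the coordinate origin (periodic wrap)
  dx <- 11.3
  s2 <- fit_membrane_profile(
    data.frame(x = (x + dx) %% Lx, y = y, z = z), c(Lx, Ly))
  expect_equal(mean_curvature(s2, (qx + dx) %% Lx, qy),
               mean_curvature(s0, qx, qy), tolerance = 1e-8)
})

test_that("residual RMS never increases with Fourier order", {
  set.seed(5)
  x <- runif(3000, 0, 63); y <- runif(3000, 0, 28)
  z <- 5 * sin(2 * pi * x / 63) + 0.4 * sin(2 * pi * (2 * x / 63 + y / 28)) +
    rnorm(3000, 0, 0.3)
  chain <- list(c(1, 0), c(1, 1), c(2, 1), c(4, 2), c(6, 2))
  rms <- vapply(chain, function(o) {
    fit_membrane_profile(data.frame(x = x, y = y, z = z), c(63, 28), o)$rms
  }, 0)
  expect_true(all(diff(rms) <= 1e-12))
})

test_that("mean curvature integrates to zero over a full buckle period", {
  set.seed(6)
  x <- runif(4000, 0, 63); y <- runif(4000, 0, 28)
  z <- 6 * sin(2 * pi * x / 63)
  s <- fit_membrane_profile(data.frame(x = x, y = y, z = z), c(63, 28),
                            orders = c(6, 2))
  gx <- seq(0, 63, length.out = 2001)[-2001]
  expect_lt(abs(mean(mean_curvature(s, gx, rep(14, 2000)))), 1e-6)
})

test_that("underdetermined fits and degenerate boxes are rejected", {
  pts <- data.frame(x = runif(10), y = runif(10), z = runif(10))
  expect_error(fit_membrane_profile(pts, c(63, 28), c(6, 2)), "underdetermined")
  expect_error(fit_membrane_profile(pts, c(0, 28), c(1, 0)), "degenerate")
})

test_that("probe curvature sampling separates biased from unbiased probes", {
  traj0 <- generate_buckled_membrane(
    buckle_ground_truth(probe_bias = 0, n_frames = 120, lipid_count = 2000,
                        seed = 5))
  cs0 <- sample_probe_curvature(traj0, n_random = 3)
  expect_equal(sum(cs0$histogram$probe), 1, tolerance = 1e-12)
  expect_equal(sum(cs0$histogram$random), 1, tolerance = 1e-12)
  expect_gt(suppressWarnings(
    ks.test(cs0$probe_H, cs0$random_H)$p.value), 0.05)

  gaps <- vapply(c(25, 100), function(b) {
    tb <- generate_buckled_membrane(
      buckle_ground_truth(probe_bias = b, n_frames = 60, lipid_count = 2000,
                          seed = 6))
    cb <- sample_probe_curvature(tb)
    cb$mean_probe - cb$mean_random
  }, 0)
  expect_true(all(gaps > 0))
  expect_gt(gaps[2], gaps[1])

  expect_error(sample_probe_curvature(traj0, equilibration_cut = 1e9),
               "pre-equilibration")
})

test_that("insertion depth recovers the imposed offset", {
  # probe at the phosphate level
  t0 <- generate_buckled_membrane(
    buckle_ground_truth(probe_bias = 0, probe_z_offset = 0, n_frames = 100,
                        seed = 7))
  d0 <- insertion_depth(t0)
  expect_lt(abs(d0$mean_offset), 0.06)

  # probe inserted 0.4 nm below the level of a 2 nm monolayer: -20%
  t1 <- generate_buckled_membrane(
    buckle_ground_truth(probe_bias = 0, probe_z_offset = -0.4, n_frames = 100,
                        seed = 8))
  d1 <- insertion_depth(t1)
  expect_equal(d1$mean_offset, -0.4, tolerance = 0.05)
  expect_equal(d1$depth_fraction_pct, -20, tolerance = 0.05 * 20)

  expect_error(insertion_depth(t1, radius = 0.01), "no phosphates")
})
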