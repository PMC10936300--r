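test_that("config invariants are enforced", {
  expect_error(synthetic_config(speeds = c(0.5, 0.5, 1)), "distinct")
  expect_error(synthetic_config(speeds = c(-1, 1)), "positive")
  expect_error(synthetic_config(fs_analog = 1000, fps_us = 500), "trigger")
  expect_error(synthetic_config(cycles_per_speed = 1), ">= 2")
})

test_that("moment profile has the stance-bump structure", {
  m <- gen_moment_profile(1.0, 1.0, 1000, noise_sd = 0)
  expect_length(m, 1000)
  expect_identical(m[1], 0)
  expect_identical(m[1000], 0)
  # exactly one interior peak: derivative changes sign once
  sgn <- sign(diff(m))
  expect_equal(sum(diff(sgn[sgn != 0]) != 0), 1)
  # peak near 75% of stance
  expect_equal(which.max(m) / 1000, 0.75, tolerance = 0.02)
  # peak grows with speed
  m_fast <- gen_moment_profile(1.50, 0.6, 1000, noise_sd = 0)
  m_slow <- gen_moment_profile(0.50, 0.8, 1000, noise_sd = 0)
  expect_gt(max(m_fast), max(m_slow))
  expect_error(gen_moment_profile(1, -1, 1000), "positive")
  expect_error(gen_moment_profile(1, 1, -5), "positive")
})

test_that("moment generation is seed-deterministic", {
  a <- with_seed(3, gen_moment_profile(1, 0.7, 1000))
  b <- with_seed(3, gen_moment_profile(1, 0.7, 1000))
  expect_identical(a, b)
})

test_that("GRF bump respects stance schedule, amplitude and threshold", {
  g <- gen_grf(list(c(0.5, 0.7)), 70, 1000)
  expect_s3_class(g, "force_trace")
  expect_true(all(g$values[1:500] == 0))
  expect_true(all(g$values[1201:length(g$values)] == 0))
  bw <- 70 * 9.81
  expect_gte(max(g$values), 1.0 * bw)
  expect_lte(max(g$values), 1.3 * bw)
  # detector recovers the schedule within +/- 2 samples (oracle scan)
  ref <- stance_scan_reference(g$values, 0.05 * bw, 200)
  expect_equal(nrow(ref), 1)
  expect_lte(abs(ref[1, 1] - 501), 2)
  expect_lte(abs(ref[1, 2] - 1200), 2)
  expect_error(gen_grf(list(c(0, 1), c(0.5, 1)), 70, 1000), "overlap")
})

test_that("sEMG is moment-modulated noise with the electromechanical lead", {
  m <- with_seed(4, gen_moment_profile(1.25, 0.65, 1000, noise_sd = 0))
  expect_error(gen_semg(m, lead_ms = 200), "150")
  e0 <- with_seed(5, gen_semg(rep(0, 650), 3, 50, 1000))
  e1 <- with_seed(5, gen_semg(m, 3, 50, 1000))
  # zero moment: activity stays at the baseline floor
  expect_true(all(sqrt(rowMeans(e0^2)) < sqrt(rowMeans(e1^2))))
  # determinism
  e2 <- with_seed(5, gen_semg(m, 3, 50, 1000))
  expect_identical(e1, e2)
  # cross-correlation between mean rectified envelope and moment peaks near
  # -lead samples (oracle: argmax of the full cross-correlation)
  e <- with_seed(6, gen_semg(m, 12, 50, 1000))
  env <- colMeans(abs(e))
  env <- stats::filter(env, rep(1 / 81, 81), sides = 2)
  env[is.na(env)] <- 0
  cc <- stats::ccf(as.numeric(env), m, lag.max = 150, plot = FALSE)
  best <- cc$lag[which.max(cc$acf)]
  expect_lte(abs(best - (-50)), 12)
})

test_that("image sequence encodes the moment monotonically", {
  cfg <- synthetic_config(fs_analog = 100, speckle_sd = 0, frame_noise_sd = 0)
  m <- gen_moment_profile(1.0, 0.7, 100, noise_sd = 0)
  imgs <- gen_us_sequence(m, cfg)
  expect_equal(dim(imgs), c(100, 100, length(m)))
  expect_error(gen_us_sequence(numeric(0), cfg), "non-empty")
  # equal moments, noise off -> identical band geometry
  m2 <- c(10, 20, 10)
  im2 <- gen_us_sequence(m2, cfg, peak_norm = 40)
  expect_identical(im2[, , 1], im2[, , 3])
  # band angle at peak moment exceeds band angle at zero moment
  # (oracle: dominant orientation from the image gradient structure tensor)
  a_peak <- dominant_band_angle(imgs[, , which.max(m)])
  a_zero <- dominant_band_angle(imgs[, , 2])
  expect_gt(a_peak, a_zero)
  # mean absolute image difference tracks moment difference (rank corr)
  idx <- seq(2, length(m), by = 4)
  ref <- idx[1]
  d_img <- vapply(idx, function(i) mean(abs(imgs[, , i] - imgs[, , ref])),
                  numeric(1))
  d_mom <- abs(m[idx] - m[ref])
  expect_gt(stats::cor(d_img, d_mom, method = "spearman"), 0.9)
})

test_that("full dataset is aligned, speed-structured and deterministic", {
  ds <- scaled_dataset()
  expect_length(ds$cycles, 5 * 8)
  for (cc in ds$cycles) {
    n <- length(cc$moment)
    expect_identical(dim(cc$frames)[3], as.integer(n))
    expect_identical(ncol(cc$emg), as.integer(n))
    expect_length(cc$grf, n)
    expect_identical(cc$moment[1], 0)
    expect_identical(cc$moment[n], 0)
  }
  # stance duration decreases with speed
  n_slow <- length(ds$cycles[[1]]$moment)                 # 0.50 m/s
  n_fast <- length(ds$cycles[[length(ds$cycles)]]$moment) # 1.50 m/s
  expect_gt(n_slow, n_fast)
  # bit-identical regeneration from the same seed
  ds2 <- gen_walking_dataset(scaled_config(seed = 7))
  expect_identical(ds$cycles[[17]]$frames, ds2$cycles[[17]]$frames)
  expect_identical(ds$cycles[[3]]$emg, ds2$cycles[[3]]$emg)
  expect_identical(ds$peak_moment, ds2$peak_moment)
})

test_that("rf mode emits beamformable channel data per moment sample", {
  cfg <- synthetic_config(fs_analog = 100, rf_mode = TRUE)
  geom <- transducer_geometry(element_count = 16)
  rfs <- gen_us_sequence(c(5, 50), cfg, peak_norm = 100, geometry = geom)
  expect_length(rfs, 2)
  expect_s3_class(rfs[[1]], "rf_frame")
  expect_identical(nrow(rfs[[1]]$samples), 16L)
})
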