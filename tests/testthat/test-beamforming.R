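small_geom <- transducer_geometry(element_count = 24)

test_that("geometry validation rejects inconsistent arrays", {
  expect_error(transducer_geometry(speed_of_sound = -1), "positive")
  expect_error(transducer_geometry(element_count = 64, pitch = 1,
                                   aperture_width = 38), "pitch")
  expect_error(rf_frame(matrix(0, 10, 5), small_geom), "element_count")
})

test_that("DAS focuses a point scatterer at its physical location", {
  rf <- simulate_point_rf(data.frame(x_mm = 0, z_mm = 20, amp = 1), small_geom)
  grid <- list(x_mm = seq(-5, 5, by = 0.2), z_mm = seq(15, 25, by = 0.2),
               pixel_pitch = 0.2)
  img <- envelope_logcompress(das_beamform(rf, grid))
  pk <- which(img$pixels == max(img$pixels), arr.ind = TRUE)
  expect_lte(abs(grid$z_mm[pk[1]] - 20), 0.2)   # +/- 1 px
  expect_lte(abs(grid$x_mm[pk[2]] - 0), 0.2)
})

test_that("vectorized DAS equals the brute-force per-pixel oracle", {
  set.seed(21)
  rf <- simulate_point_rf(
    data.frame(x_mm = c(-4, 1, 5), z_mm = c(16, 21, 24), amp = c(1, 0.7, 1.2)),
    small_geom)
  grid <- list(x_mm = seq(-6, 6, length.out = 64),
               z_mm = seq(14, 26, length.out = 64), pixel_pitch = 12 / 63)
  fast <- das_beamform(rf, grid)
  slow <- das_reference(rf, grid)
  expect_lt(max(abs(fast - slow)), 1e-9 * max(abs(slow)))
})

test_that("DAS is linear and symmetric", {
  rf1 <- simulate_point_rf(data.frame(x_mm = -3, z_mm = 18, amp = 1), small_geom)
  rf2 <- simulate_point_rf(data.frame(x_mm = 2, z_mm = 22, amp = 1), small_geom)
  grid <- list(x_mm = seq(-5, 5, by = 0.5), z_mm = seq(15, 25, by = 0.5),
               pixel_pitch = 0.5)
  a <- 2.5; b <- -1.25
  mix <- rf_frame(a * rf1$samples + b * rf2$samples, small_geom)
  lhs <- das_beamform(mix, grid)
  rhs <- a * das_beamform(rf1, grid) + b * das_beamform(rf2, grid)
  expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 1e-12)
  # all-zero RF -> all-zero image
  rf0 <- rf_frame(matrix(0, 24, 200), small_geom)
  expect_true(all(das_beamform(rf0, grid) == 0))
  # mirrored scatterers -> left-right mirror image
  rfs <- simulate_point_rf(data.frame(x_mm = c(-5, 5), z_mm = 20, amp = 1),
                           small_geom)
  sym_grid <- list(x_mm = seq(-8, 8, by = 0.25), z_mm = seq(16, 24, by = 0.25),
                   pixel_pitch = 0.25)
  bm <- das_beamform(rfs, sym_grid)
  expect_lt(max(abs(bm - bm[, ncol(bm):1])), 1e-9 * max(abs(bm)))
})

test_that("log compression maps the stated dynamic range onto [0, 1]", {
  # integer-cycle carrier columns: the axial analytic signal has a constant
  # envelope equal to the amplitude, so the pixel value follows the mapping
  # 1 + 20*log10(ratio)/DR exactly (0.1 of max at 60 dB -> 2/3)
  t <- 0:255
  carrier <- cos(2 * pi * 50 * t / 256)
  bf <- cbind(carrier, 0.1 * carrier)
  img <- envelope_logcompress(bf, dynamic_range = 60)
  expect_equal(max(img$pixels), 1.0)
  expect_equal(img$pixels[, 1], rep(1, 256), tolerance = 1e-9)
  expect_equal(img$pixels[, 2], rep(2 / 3, 256), tolerance = 1e-9)
  # all-zero input maps to all-zero image
  expect_true(all(envelope_logcompress(matrix(0, 32, 8))$pixels == 0))
  # monotone in envelope, and the bottom of the dynamic range maps to 0
  bf3 <- cbind(carrier, 0.5 * carrier, 1e-4 * carrier)
  img3 <- envelope_logcompress(bf3, dynamic_range = 60)
  expect_true(mean(img3$pixels[, 1]) > mean(img3$pixels[, 2]))
  expect_equal(img3$pixels[, 3], rep(0, 256))
  expect_error(envelope_logcompress(bf, dynamic_range = 0), "positive")
})

test_that("ROI cropping follows the physical grid with tie-break to smaller", {
  # default 0.1 mm/px grid: 500 rows x 380 cols
  geom <- transducer_geometry()
  grid <- bmode_grid(geom)
  expect_length(grid$z_mm, 500)
  expect_length(grid$x_mm, 380)
  px <- outer(seq_len(500), seq_len(380), function(r, cc) r * 1000 + cc)
  img <- structure(list(pixels = px, x_mm = grid$x_mm, z_mm = grid$z_mm,
                        pixel_pitch = c(0.1, 0.1), timestamp = 0),
                   class = "bmode_image")
  patch <- crop_roi(img, roi_spec(c(100, 100), c(0, 20)))
  expect_equal(dim(patch), c(100, 100))
  # rows 150-249, cols 140-239 (0-based) = 151-250, 141-240 (1-based)
  expect_identical(patch[1, 1], px[151, 141])
  expect_identical(patch[100, 100], px[250, 240])
  # identity crop
  full <- crop_roi(img, roi_spec(c(500, 380), c(0, 25)))
  expect_identical(full, px)
  # bottom-edge violation for a deep 300x300 ROI
  expect_error(crop_roi(img, roi_spec(c(300, 300), c(0, 45))), "bottom")
  expect_error(crop_roi(img, roi_spec(c(300, 300), c(-15, 20))), "left")
  # requested size is always honored
  for (sz in c(31, 200, 299)) {
    expect_equal(dim(crop_roi(img, roi_spec(c(sz, sz), c(0, 25)))), c(sz, sz))
  }
})
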