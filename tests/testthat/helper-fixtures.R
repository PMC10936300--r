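# Shared fixtures, generated in code. The scaled dataset uses a 100 Hz
# frame/analog rate so a full five-speed, eight-cycle dataset stays small
# enough for fast tests while keeping every invariant of the full protocol.

scaled_config <- function(seed = 7, ...) {
  synthetic_config(fs_analog = 100, seed = seed, ...)
}

# cached scaled dataset shared by the heavier tests
scaled_dataset <- local({
  ds <- NULL
  function(seed = 7) {
    if (is.null(ds) || ds$seed != seed) ds <<- gen_walking_dataset(scaled_config(seed))
    ds
  }
})

# training schedule for the scaled end-to-end runs
scaled_train_config <- function() {
  train_config(mini_batch = 64, max_epochs = 5, lr_initial = 0.003,
               lr_final = 3e-4, lr_drop_epoch = 4)
}

# brute-force per-pixel delay-and-sum, written independently of the
# vectorized implementation (plain loops over pixels and elements)
das_reference <- function(rf, grid) {
  geom <- rf$geometry
  fs <- geom$sampling_rate * 1e6
  c0 <- geom$speed_of_sound
  xe <- ((seq_len(geom$element_count)) - (geom$element_count + 1) / 2) *
    geom$pitch * 1e-3
  ns <- ncol(rf$samples)
  out <- matrix(0, length(grid$z_mm), length(grid$x_mm))
  for (zi in seq_along(grid$z_mm)) {
    for (xi in seq_along(grid$x_mm)) {
      z <- grid$z_mm[zi] * 1e-3
      x <- grid$x_mm[xi] * 1e-3
      acc <- 0
      for (e in seq_len(geom$element_count)) {
        tau <- (z + sqrt((x - xe[e])^2 + z^2)) / c0
        s <- tau * fs + 1
        i0 <- floor(s)
        fr <- s - i0
        v0 <- if (i0 >= 1 && i0 <= ns) rf$samples[e, i0] else 0
        v1 <- if (i0 + 1 >= 1 && i0 + 1 <= ns) rf$samples[e, i0 + 1] else 0
        acc <- acc + (1 - fr) * v0 + fr * v1
      }
      out[zi, xi] <- acc
    }
  }
  out
}

# brute-force threshold scan oracle for stance detection
stance_scan_reference <- function(values, threshold, min_len) {
  above <- values >= threshold
  events <- NULL
  i <- 1L
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) events <- rbind(events, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  events
}

# dominant gradient orientation of a grating image, degrees from vertical
dominant_band_angle <- function(img) {
  gx <- img[, -1] - img[, -ncol(img)]
  gy <- img[-1, ] - img[-nrow(img), ]
  gx <- gx[-nrow(gx), ]
  gy <- gy[, -ncol(gy)]
  jxx <- sum(gx^2); jyy <- sum(gy^2); jxy <- sum(gx * gy)
  phi <- 0.5 * atan2(2 * jxy, jxx - jyy)  # gradient direction vs x-axis
  90 - abs(phi) * 180 / pi
}
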