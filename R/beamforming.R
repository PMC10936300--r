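#' Linear-array transducer geometry
#'
#' Physical description of the plane-wave imaging setup: a 38 mm linear
#' array at 6.4 MHz center frequency imaging to 50 mm depth. The speed of
#' sound defaults to the standard soft-tissue value of 1540 m/s.
#'
#' @param element_count number of array elements.
#' @param pitch element pitch in mm; defaults to
#'   `aperture_width / element_count`.
#' @param aperture_width array width in mm.
#' @param center_frequency transmit center frequency in MHz.
#' @param sampling_rate RF sampling rate in MHz.
#' @param speed_of_sound speed of sound in m/s.
#' @param imaging_depth imaging depth in mm.
#' @return An object of class `transducer_geometry`.
#' @export
transducer_geometry <- function(element_count = 128L,
                                pitch = aperture_width / element_count,
                                aperture_width = 38,
                                center_frequency = 6.4,
                                sampling_rate = 25.6,
                                speed_of_sound = 1540,
                                imaging_depth = 50) {
  vals <- c(element_count = element_count, pitch = pitch,
            aperture_width = aperture_width,
            center_frequency = center_frequency,
            sampling_rate = sampling_rate, speed_of_sound = speed_of_sound,
            imaging_depth = imaging_depth)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all transducer geometry quantities must be positive and finite",
         call. = FALSE)
  }
  if (abs(element_count * pitch - aperture_width) > 0.05 * aperture_width) {
    stop("aperture_width must be ~ element_count * pitch", call. = FALSE)
  }
  structure(list(
    element_count = as.integer(element_count), pitch = pitch,
    aperture_width = aperture_width, center_frequency = center_frequency,
    sampling_rate = sampling_rate, speed_of_sound = speed_of_sound,
    imaging_depth = imaging_depth
  ), class = "transducer_geometry")
}

#' Lateral element positions in mm (0 at the array center)
#' @param geometry a [transducer_geometry()].
#' @return Numeric vector of length `element_count`.
#' @export
element_positions <- function(geometry) {
  n <- geometry$element_count
  (seq_len(n) - (n + 1) / 2) * geometry$pitch
}

#' Construct a raw plane-wave RF frame
#'
#' @param samples `element_count x n_samples` real matrix of RF channel data.
#' @param geometry a [transducer_geometry()].
#' @param t0 acquisition start time in s.
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(samples, geometry, t0 = 0) {
  stopifnot(inherits(geometry, "transducer_geometry"))
  if (nrow(samples) != geometry$element_count) {
    stop("rf frame row count must equal element_count", call. = FALSE)
  }
  if (!all(is.finite(samples))) stop("rf samples must be finite", call. = FALSE)
  structure(list(samples = samples, geometry = geometry, t0 = t0),
            class = "rf_frame")
}

#' Simulate plane-wave RF channel data for point scatterers
#'
#' Time-of-flight forward model for a single zero-angle plane-wave transmit:
#' each element records a Gaussian-enveloped tone at
#' `(z + sqrt((x - x_e)^2 + z^2)) / c` for each scatterer. Used to test the
#' delay-and-sum beamformer against a known target.
#'
#' @param scatterers matrix/data.frame with columns `x_mm`, `z_mm`, `amp`.
#' @param geometry a [transducer_geometry()].
#' @param t0 acquisition start time in s.
#' @param n_samples number of time samples; defaults to covering twice the
#'   imaging depth plus the pulse tail.
#' @return An [rf_frame()].
#' @export
simulate_point_rf <- function(scatterers, geometry, t0 = 0, n_samples = NULL) {
  sc <- as.matrix(as.data.frame(scatterers)[, c("x_mm", "z_mm", "amp")])
  fs <- geometry$sampling_rate * 1e6
  f0 <- geometry$center_frequency * 1e6
  c0 <- geometry$speed_of_sound
  if (is.null(n_samples)) {
    tmax <- 2.2 * geometry$imaging_depth * 1e-3 / c0 + 4 / f0
    n_samples <- ceiling(tmax * fs)
  }
  xe <- element_positions(geometry) * 1e-3
  t <- (seq_len(n_samples) - 1) / fs
  sig <- 0.5 / f0  # pulse envelope width
  rf <- matrix(0, geometry$element_count, n_samples)
  for (s in seq_len(nrow(sc))) {
    x <- sc[s, "x_mm"] * 1e-3
    z <- sc[s, "z_mm"] * 1e-3
    tof <- (z + sqrt((x - xe)^2 + z^2)) / c0
    for (e in seq_len(geometry$element_count)) {
      dt <- t - tof[e]
      rf[e, ] <- rf[e, ] +
        sc[s, "amp"] * exp(-dt^2 / (2 * sig^2)) * cos(2 * pi * f0 * dt)
    }
  }
  rf_frame(rf, geometry, t0 = t0)
}

#' Default B-mode pixel grid for a geometry
#'
#' Isotropic grid: lateral pixel centers run from `-aperture/2` in steps of
#' `pixel_pitch`, axial centers from 0 (skin) downward. The default 0.1 mm/px
#' gives 500 rows x 380 cols for the 50 mm x 38 mm footprint.
#'
#' @param geometry a [transducer_geometry()].
#' @param pixel_pitch pixel size in mm/px.
#' @return List with `x_mm` (lateral centers), `z_mm` (axial centers),
#'   `pixel_pitch`.
#' @export
bmode_grid <- function(geometry, pixel_pitch = 0.1) {
  n_cols <- round(geometry$aperture_width / pixel_pitch)
  n_rows <- round(geometry$imaging_depth / pixel_pitch)
  list(
    x_mm = -geometry$aperture_width / 2 + (seq_len(n_cols) - 1) * pixel_pitch,
    z_mm = (seq_len(n_rows) - 1) * pixel_pitch,
    pixel_pitch = pixel_pitch
  )
}

#' Delay-and-sum beamforming of a plane-wave RF frame
#'
#' For each pixel, sums the element signals at the plane-wave transmit delay
#' (`z / c`) plus the receive delay (`||p - e|| / c`), with sub-sample linear
#' interpolation (nearest-neighbor optional) and no apodization. Delays that
#' fall beyond the recorded samples contribute zero.
#'
#' @param rf an [rf_frame()].
#' @param grid a pixel grid from [bmode_grid()] (or a list with `x_mm`,
#'   `z_mm`, `pixel_pitch`).
#' @param interp `"linear"` or `"nearest"` sub-sample delay handling.
#' @return Real matrix `length(z_mm) x length(x_mm)` of summed RF (pre
#'   envelope detection), with grid coordinates attached as attributes.
#' @export
das_beamform <- function(rf, grid = bmode_grid(rf$geometry),
                         interp = c("linear", "nearest")) {
  stopifnot(inherits(rf, "rf_frame"))
  interp <- match.arg(interp)
  geom <- rf$geometry
  fs <- geom$sampling_rate * 1e6
  c0 <- geom$speed_of_sound
  x <- grid$x_mm * 1e-3
  z <- grid$z_mm * 1e-3
  xe <- element_positions(geom) * 1e-3
  ns <- ncol(rf$samples)
  nz <- length(z)
  nx <- length(x)
  out <- matrix(0, nz, nx)
  zc <- matrix(z, nz, nx)                     # transmit path per pixel
  xm <- matrix(x, nz, nx, byrow = TRUE)
  for (e in seq_len(geom$element_count)) {
    rx <- sqrt((xm - xe[e])^2 + zc^2)
    s <- (zc + rx) / c0 * fs + 1              # fractional sample index
    if (interp == "nearest") {
      i0 <- round(s)
      ok <- i0 >= 1 & i0 <= ns
      v <- matrix(0, nz, nx)
      v[ok] <- rf$samples[e, i0[ok]]
    } else {
      i0 <- floor(s)
      fr <- s - i0
      ok0 <- i0 >= 1 & i0 <= ns
      ok1 <- (i0 + 1) >= 1 & (i0 + 1) <= ns
      v0 <- matrix(0, nz, nx); v0[ok0] <- rf$samples[e, i0[ok0]]
      v1 <- matrix(0, nz, nx); v1[ok1] <- rf$samples[e, i0[ok1] + 1]
      v <- (1 - fr) * v0 + fr * v1
    }
    out <- out + v
  }
  attr(out, "x_mm") <- grid$x_mm
  attr(out, "z_mm") <- grid$z_mm
  attr(out, "pixel_pitch") <- grid$pixel_pitch
  out
}

# analytic signal (FFT Hilbert) of a real vector
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Envelope detection and log compression to a B-mode image
#'
#' The envelope is the magnitude of the axial analytic signal; the image is
#' `clamp(1 + 20 log10(env / env_max) / dynamic_range, 0, 1)`, mapping the
#' top `dynamic_range` dB of envelope onto \[0, 1\]. An all-zero input maps
#' to an all-zero image.
#'
#' @param beamformed real matrix from [das_beamform()] (rows = axial).
#' @param dynamic_range display dynamic range in dB (> 0).
#' @param timestamp frame time in s.
#' @return An object of class `bmode_image` with `pixels` in \[0, 1\],
#'   `pixel_pitch` (mm/px, axial and lateral), and `timestamp`.
#' @export
envelope_logcompress <- function(beamformed, dynamic_range = 60, timestamp = 0) {
  if (dynamic_range <= 0) stop("dynamic_range must be positive", call. = FALSE)
  env <- apply(beamformed, 2, function(col) Mod(analytic_signal(col)))
  env <- matrix(env, nrow(beamformed), ncol(beamformed))
  emax <- max(env)
  if (emax == 0) {
    px <- matrix(0, nrow(env), ncol(env))
  } else {
    px <- 1 + 20 * log10(env / emax) / dynamic_range
    px <- pmin(pmax(px, 0), 1)
  }
  pp <- attr(beamformed, "pixel_pitch")
  if (is.null(pp)) pp <- NA_real_
  structure(list(
    pixels = px,
    pixel_pitch = c(axial = pp, lateral = pp),
    x_mm = attr(beamformed, "x_mm"),
    z_mm = attr(beamformed, "z_mm"),
    timestamp = timestamp
  ), class = "bmode_image")
}

#' Region-of-interest specification in physical coordinates
#'
#' @param size_px `c(height, width)` in pixels.
#' @param center_mm `c(lateral, depth)` in mm (lateral 0 at the transducer
#'   center, depth 0 at the skin).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(size_px = c(100L, 100L), center_mm = c(0, 20)) {
  if (any(size_px <= 0)) stop("ROI size must be positive", call. = FALSE)
  structure(list(size_px = as.integer(size_px), center_mm = center_mm),
            class = "roi_spec")
}

# nearest pixel index (1-based) for physical coordinate; ties toward the
# smaller index
nearest_index <- function(target, coords) {
  pitch <- coords[2] - coords[1]
  d <- (target - coords[1]) / pitch
  i0 <- ceiling(d - 0.5) + 1
  if (i0 < 1 || i0 > length(coords)) return(NA_integer_)
  as.integer(i0)
}

#' Crop a physical-coordinate ROI from a B-mode image
#'
#' Pure windowing (no resampling): the ROI center in mm is mapped to the
#' nearest pixel (ties toward the smaller index) and a patch of exactly
#' `size_px` is extracted, spanning `center - floor(size/2)` to
#' `center + ceiling(size/2) - 1`.
#'
#' @param image a [bmode_image()] (or a matrix with `x_mm`/`z_mm` attributes).
#' @param roi a [roi_spec()].
#' @return Matrix patch of exactly `size_px`.
#' @export
crop_roi <- function(image, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  if (inherits(image, "bmode_image")) {
    px <- image$pixels; x_mm <- image$x_mm; z_mm <- image$z_mm
  } else {
    px <- image; x_mm <- attr(image, "x_mm"); z_mm <- attr(image, "z_mm")
  }
  if (is.null(x_mm) || is.null(z_mm)) {
    stop("image lacks physical pixel coordinates", call. = FALSE)
  }
  ci <- nearest_index(roi$center_mm[2], z_mm)  # depth -> row
  cj <- nearest_index(roi$center_mm[1], x_mm)  # lateral -> col
  if (is.na(ci) || is.na(cj)) {
    stop("ROI center lies outside the image", call. = FALSE)
  }
  h <- roi$size_px[1]; w <- roi$size_px[2]
  r0 <- ci - floor(h / 2); r1 <- r0 + h - 1L
  c0 <- cj - floor(w / 2); c1 <- c0 + w - 1L
  if (r0 < 1) stop("ROI exceeds the top edge of the image", call. = FALSE)
  if (r1 > nrow(px)) stop("ROI exceeds the bottom edge of the image", call. = FALSE)
  if (c0 < 1) stop("ROI exceeds the left edge of the image", call. = FALSE)
  if (c1 > ncol(px)) stop("ROI exceeds the right edge of the image", call. = FALSE)
  px[r0:r1, c0:c1, drop = FALSE]
}
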