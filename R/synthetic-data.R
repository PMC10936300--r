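#' Configuration for the synthetic walking-data generator
#'
#' Describes the study conditions the generator emulates: five treadmill
#' speeds, eight stance cycles per speed, 1000 Hz analog channels
#' trigger-synchronized with 1000 frames/s ultrasound imaging, and a net
#' plantarflexion moment whose peak grows with walking speed.
#'
#' @param speeds walking speeds in m/s.
#' @param cycles_per_speed stance cycles generated per speed (>= 2).
#' @param fs_analog analog sampling rate in Hz (GRF, sEMG, moment labels).
#' @param fps_us ultrasound frame rate in frames/s; must equal `fs_analog`
#'   (the modalities are trigger-synchronized).
#' @param body_mass subject body mass in kg.
#' @param peak_moment_base baseline peak plantarflexion moment in Nm.
#' @param peak_moment_per_speed increase of the peak moment per m/s of
#'   walking speed, in Nm/(m/s).
#' @param moment_noise_sd relative SD of cycle-to-cycle peak-moment noise.
#' @param semg_channels number of sEMG channels (LGS, MGS, SOL).
#' @param semg_lead_ms electromechanical lead of sEMG over moment, ms
#'   (within the physiological 30--150 ms window).
#' @param image_height_px,image_width_px muscle-image size in pixels.
#' @param speckle_sd log-amplitude SD of the static multiplicative speckle
#'   field (0 disables speckle).
#' @param frame_noise_sd SD of additive per-frame image noise (0 disables).
#' @param rf_mode if `TRUE`, `gen_us_sequence()` emits raw point-scatterer RF
#'   channel data instead of images (for beamformer tests).
#' @param seed integer root seed; all modality substreams derive from it.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(speeds = c(0.50, 0.75, 1.00, 1.25, 1.50),
                             cycles_per_speed = 8L,
                             fs_analog = 1000,
                             fps_us = fs_analog,
                             body_mass = 70,
                             peak_moment_base = 60,
                             peak_moment_per_speed = 50,
                             moment_noise_sd = 0.03,
                             semg_channels = 3L,
                             semg_lead_ms = 50,
                             image_height_px = 100L,
                             image_width_px = 100L,
                             speckle_sd = 0.35,
                             frame_noise_sd = 0.01,
                             rf_mode = FALSE,
                             seed = 1L) {
  if (any(speeds <= 0)) stop("speeds must be strictly positive", call. = FALSE)
  if (anyDuplicated(speeds)) stop("speeds must be distinct", call. = FALSE)
  if (fs_analog != fps_us) {
    stop("fs_analog must equal fps_us (trigger-synchronized acquisition)",
         call. = FALSE)
  }
  if (cycles_per_speed < 2) stop("cycles_per_speed must be >= 2", call. = FALSE)
  if (fs_analog <= 0) stop("fs_analog must be positive", call. = FALSE)
  if (body_mass <= 0) stop("body_mass must be positive", call. = FALSE)
  cfg <- list(
    speeds = sort(speeds), cycles_per_speed = as.integer(cycles_per_speed),
    fs_analog = fs_analog, fps_us = fps_us, body_mass = body_mass,
    peak_moment_base = peak_moment_base,
    peak_moment_per_speed = peak_moment_per_speed,
    moment_noise_sd = moment_noise_sd,
    semg_channels = as.integer(semg_channels), semg_lead_ms = semg_lead_ms,
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    speckle_sd = speckle_sd, frame_noise_sd = frame_noise_sd,
    rf_mode = isTRUE(rf_mode), seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Stance duration as a function of walking speed
#'
#' Linear decrease from 0.8 s at 0.50 m/s to 0.55 s at 1.50 m/s, reflecting
#' the shorter stance (fewer image frames) at faster walking.
#'
#' @param speed walking speed in m/s.
#' @return Stance duration in seconds.
#' @export
stance_duration_for_speed <- function(speed) {
  0.925 - 0.25 * speed
}

#' Generate one stance-cycle net plantarflexion moment profile
#'
#' A smooth sin^2-type bump that is zero at heel-strike and toe-off and peaks
#' near 75% of stance (the push-off). The peak value grows linearly with
#' walking speed and is perturbed by seeded cycle-to-cycle noise.
#'
#' @param speed walking speed in m/s.
#' @param stance_duration stance duration in seconds (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @param config a [synthetic_config()].
#' @param noise_sd relative SD of the peak perturbation; defaults to the
#'   config value. Uses the current RNG stream.
#' @return Numeric moment trace in Nm with `round(stance_duration * fs)`
#'   samples, zero at both ends, one interior peak.
#' @export
gen_moment_profile <- function(speed, stance_duration, fs,
                               config = synthetic_config(),
                               noise_sd = config$moment_noise_sd) {
  if (stance_duration <= 0) stop("stance_duration must be positive", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  n <- round(stance_duration * fs)
  if (n < 3) stop("stance window too short for the sampling rate", call. = FALSE)
  tau <- seq(0, 1, length.out = n)
  # exponent placing the peak of sin(pi * tau^k)^2 at tau = 0.75
  k <- log(0.5) / log(0.75)
  peak <- config$peak_moment_base + config$peak_moment_per_speed * speed
  if (noise_sd > 0) peak <- peak * (1 + stats::rnorm(1, 0, noise_sd))
  m <- peak * sin(pi * tau^k)^2
  m[1] <- 0
  m[n] <- 0
  m
}

#' Generate a vertical ground reaction force trace for scheduled stances
#'
#' Each stance window holds a double-peaked force bump with a maximum of
#' about 1.1 body weight; the trace is identically zero outside stance, and
#' within stance exceeds the 5% body-weight detection threshold except for
#' sample-scale ramps at the edges, so threshold-based event detection
#' recovers the schedule exactly.
#'
#' @param stance_schedule list of `c(start_s, duration_s)` pairs
#'   (non-overlapping).
#' @param body_mass body mass in kg.
#' @param fs sampling rate in Hz.
#' @param noise_sd SD of additive in-stance force noise in N (default 0).
#' @param total_duration total trace length in s; defaults to the last
#'   stance end plus 0.3 s.
#' @return A [force_trace()] in N.
#' @export
gen_grf <- function(stance_schedule, body_mass, fs, noise_sd = 0,
                    total_duration = NULL) {
  starts <- vapply(stance_schedule, `[`, numeric(1), 1L)
  durs <- vapply(stance_schedule, `[`, numeric(1), 2L)
  if (any(durs <= 0)) stop("stance durations must be positive", call. = FALSE)
  ord <- order(starts)
  starts <- starts[ord]; durs <- durs[ord]
  if (length(starts) > 1 &&
      any(starts[-1] < (starts + durs)[-length(starts)])) {
    stop("stance windows overlap", call. = FALSE)
  }
  if (is.null(total_duration)) total_duration <- max(starts + durs) + 0.3
  n <- round(total_duration * fs)
  f <- numeric(n)
  bw <- body_mass * 9.81
  # double-peaked stance shape; smax normalizes the maximum to 1.1 body weight
  shape <- function(tau) sqrt(sin(pi * tau)) * (1 + 0.4 * cos(2 * pi * tau))
  smax <- max(shape(seq(0, 1, length.out = 2001)))
  for (i in seq_along(starts)) {
    i0 <- floor(starts[i] * fs) + 1L          # first sample at/after start
    i1 <- ceiling((starts[i] + durs[i]) * fs) # last sample before end
    idx <- seq.int(i0, i1)
    t <- (idx - 1) / fs
    tau <- (t - starts[i]) / durs[i]
    keep <- tau > 0 & tau < 1
    vals <- 1.1 * bw * shape(tau[keep]) / smax
    if (noise_sd > 0) vals <- pmax(vals + stats::rnorm(length(vals), 0, noise_sd), 0)
    f[idx[keep]] <- vals
  }
  force_trace(f, fs = fs, t0 = 0)
}

#' Generate multi-channel surface EMG synchronized with a moment trace
#'
#' Zero-mean broadband noise band-limited to 20--450 Hz (capped below the
#' Nyquist frequency), amplitude-modulated by the moment envelope advanced by
#' the electromechanical lead; channel gains differ by seeded factors.
#'
#' @param moment moment trace in Nm.
#' @param channels number of channels.
#' @param lead_ms electromechanical lead in ms, within \[0, 150\].
#' @param fs sampling rate in Hz.
#' @param baseline relative baseline activity floor (default 0.05).
#' @return A `channels x length(moment)` matrix (mV), with channel names
#'   `LGS`, `MGS`, `SOL`, then `CH4`, ... for extra channels.
#' @export
gen_semg <- function(moment, channels = 3L, lead_ms = 50, fs = 1000,
                     baseline = 0.05) {
  if (lead_ms < 0 || lead_ms > 150) {
    stop("lead_ms must lie within [0, 150] ms", call. = FALSE)
  }
  n <- length(moment)
  if (n < 8) stop("moment trace too short", call. = FALSE)
  pk <- max(abs(moment))
  env <- if (pk > 0) abs(moment) / pk else numeric(n) * 0
  lead_samp <- round(lead_ms / 1000 * fs)
  # advance: muscle activity at time t reflects the moment at t + lead
  env_adv <- c(env[seq_len(n - lead_samp) + lead_samp], rep(0, lead_samp))
  lo <- 20
  hi <- min(450, 0.45 * fs)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  gains <- stats::runif(channels, 0.7, 1.3)
  out <- matrix(0, nrow = channels, ncol = n)
  for (ch in seq_len(channels)) {
    noise <- stats::rnorm(n)
    noise <- signal::filtfilt(bf, noise)
    out[ch, ] <- gains[ch] * (baseline + env_adv) * noise
  }
  nm <- c("LGS", "MGS", "SOL")
  rownames(out) <- c(nm, sprintf("CH%d", seq_len(max(0, channels - 3)) + 3L))[seq_len(channels)]
  out
}

#' Generate a muscle-image (or RF) sequence encoding the moment trace
#'
#' One image per moment sample. Images are a multiplicative speckle
#' background times bright oblique fascicle-like bands (clipped oriented
#' gratings) whose inclination angle, spacing and brightness are
#' deterministic monotone functions of the instantaneous moment normalized
#' by `peak_norm`. With
#' `rf_mode`, emits point-scatterer RF channel data per frame instead, for
#' beamformer tests.
#'
#' @param moment moment trace in Nm (non-empty).
#' @param config a [synthetic_config()].
#' @param peak_norm normalization peak in Nm (dataset-level ground-truth
#'   peak); defaults to `max(abs(moment))`.
#' @param geometry a [transducer_geometry()]; only used in `rf_mode`.
#' @return In image mode, an `H x W x n` array with values in \[0, 1\]. In
#'   `rf_mode`, a list of RF frames (one per moment sample).
#' @export
gen_us_sequence <- function(moment, config = synthetic_config(),
                            peak_norm = max(abs(moment)),
                            geometry = NULL) {
  if (length(moment) == 0) stop("moment trace must be non-empty", call. = FALSE)
  if (config$rf_mode) {
    return(gen_rf_sequence(moment, config, peak_norm, geometry))
  }
  h <- config$image_height_px
  w <- config$image_width_px
  m <- if (peak_norm > 0) pmin(pmax(abs(moment) / peak_norm, 0), 1) else moment * 0
  Y <- matrix(seq_len(h), h, w)           # row index (axial)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)  # col index (lateral)
  speckle <- matrix(1, h, w)
  if (config$speckle_sd > 0) {
    g <- matrix(stats::rnorm(h * w), h, w)
    g <- smooth_field(g, sigma = 2)
    g <- g / stats::sd(g)
    speckle <- exp(config$speckle_sd * g)
    speckle <- speckle / mean(speckle)
  }
  out <- array(0, dim = c(h, w, length(moment)))
  for (t in seq_along(moment)) {
    theta <- (10 + 35 * m[t]) * pi / 180   # fascicle inclination, deg -> rad
    lambda <- 14 - 6 * m[t]                # band spacing in px
    amp <- 0.35 + 0.45 * m[t]              # band brightness (contraction)
    g <- cos(2 * pi * (X * sin(theta) + Y * cos(theta)) / lambda)
    bands <- pmax(g, 0)^3
    img <- speckle * (0.25 + amp * bands)
    if (config$frame_noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, config$frame_noise_sd), h, w)
    }
    out[, , t] <- pmin(pmax(img, 0), 1)
  }
  out
}

# Point-scatterer RF stack for beamformer testing: three fixed scatterers
# whose lateral position shifts with the normalized moment.
gen_rf_sequence <- function(moment, config, peak_norm, geometry) {
  if (is.null(geometry)) geometry <- transducer_geometry(element_count = 32)
  m <- if (peak_norm > 0) pmin(abs(moment) / peak_norm, 1) else moment * 0
  lapply(seq_along(moment), function(t) {
    sc <- cbind(
      x_mm = c(-5, 0, 5) + 2 * m[t],
      z_mm = c(15, 20, 25),
      amp = c(1, 1, 1)
    )
    simulate_point_rf(sc, geometry, t0 = (t - 1) / config$fps_us)
  })
}

# separable gaussian blur with reflected edges (small sigma, fixed kernel)
smooth_field <- function(x, sigma = 2) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) {
    pad <- m[c(rev(seq_len(r)), seq_len(nrow(m)), nrow(m) + 1 - seq_len(r)), , drop = FALSE]
    apply(pad, 2, function(col) stats::filter(col, k, sides = 2))[r + seq_len(nrow(m)), , drop = FALSE]
  }
  t(blur1(t(blur1(x))))
}

#' Generate a complete synchronized multi-speed walking dataset
#'
#' For each configured speed, generates `cycles_per_speed` stance cycles
#' (stance duration decreasing with speed) with sample-aligned moment labels,
#' vertical GRF, multi-channel sEMG, and a muscle-image sequence at one image
#' per analog sample. All randomness derives from the config seed via named
#' substreams, so identical configs give bit-identical datasets.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `synthetic_dataset`: list with `cycles` (one
#'   record per stance cycle: `speed`, `cycle_id`, `start_s`, `moment`,
#'   `grf`, `emg`, `frames`), `grf_traces` (per-speed full [force_trace()]s
#'   with embedded stance schedule), `peak_moment`, `config`, `seed`.
#' @export
gen_walking_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$fs_analog
  gap <- 0.3  # swing/gap between scheduled stances, s

  # pass 1: moment traces (define the dataset-level normalization peak)
  plan <- list()
  for (si in seq_along(config$speeds)) {
    sp <- config$speeds[si]
    dur <- stance_duration_for_speed(sp)
    moments <- with_seed(
      substream_seed(config$seed, paste0("moment/", format(sp))),
      lapply(seq_len(config$cycles_per_speed), function(ci) {
        gen_moment_profile(sp, dur, fs, config)
      })
    )
    starts <- 0.2 + (seq_len(config$cycles_per_speed) - 1) * (dur + gap)
    plan[[si]] <- list(speed = sp, dur = dur, starts = starts, moments = moments)
  }
  peak_moment <- max(vapply(plan, function(p) max(vapply(p$moments, max, numeric(1))),
                            numeric(1)))

  cycles <- list()
  grf_traces <- list()
  for (si in seq_along(plan)) {
    p <- plan[[si]]
    schedule <- lapply(seq_along(p$starts), function(i) c(p$starts[i], p$dur))
    grf <- gen_grf(schedule, config$body_mass, fs)
    attr(grf, "schedule") <- schedule
    grf_traces[[format(p$speed)]] <- grf
    for (ci in seq_len(config$cycles_per_speed)) {
      mo <- p$moments[[ci]]
      n <- length(mo)
      i0 <- floor(p$starts[ci] * fs) + 1L
      grf_seg <- grf$values[seq.int(i0, i0 + n - 1L)]
      emg <- with_seed(
        substream_seed(config$seed, sprintf("semg/%s/%d", format(p$speed), ci)),
        gen_semg(mo, config$semg_channels, config$semg_lead_ms, fs)
      )
      frames <- with_seed(
        substream_seed(config$seed, sprintf("us/%s/%d", format(p$speed), ci)),
        gen_us_sequence(mo, config, peak_norm = peak_moment)
      )
      nf <- if (is.list(frames)) length(frames) else dim(frames)[3]
      stopifnot(nf == n, ncol(emg) == n, length(grf_seg) == n)
      cycles[[length(cycles) + 1L]] <- list(
        speed = p$speed, cycle_id = ci, start_s = p$starts[ci],
        moment = mo, grf = grf_seg, emg = emg, frames = frames
      )
    }
  }
  structure(
    list(cycles = cycles, grf_traces = grf_traces, peak_moment = peak_moment,
         config = config, seed = config$seed,
         generator_version = "1"),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d stance cycles (%d speeds x %d cycles), fs %g Hz, seed %d\n",
    length(x$cycles), length(x$config$speeds), x$config$cycles_per_speed,
    x$config$fs_analog, x$seed))
  invisible(x)
}
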