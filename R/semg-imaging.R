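#' Zero-phase band-pass filtering of multi-channel sEMG
#'
#' 4th-order Butterworth applied forward-backward (zero phase) per channel.
#'
#' @param emg `channels x samples` matrix (rows may be named LGS/MGS/SOL).
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order filter order (per direction).
#' @return Filtered matrix of the same shape and dimnames.
#' @export
bandpass_emg <- function(emg, low = 20, high = 450, fs = 1000, order = 4) {
  if (!is.matrix(emg)) emg <- matrix(emg, nrow = 1)
  if (low <= 0 || high <= low || high >= fs / 2) {
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(emg, 1, function(ch) signal::filtfilt(bf, ch)))
  dimnames(out) <- dimnames(emg)
  out
}

#' Analytic Morlet wavelet matrix for windowed scalograms
#'
#' Precomputes, for integer scales `1..n_scales`, the conjugated wavelet
#' sampled at every (shift, sample) pair of a length-`window_len` window, so
#' a whole scalogram is one matrix product. The analytic Morlet has center
#' angular frequency `omega0` (default 6), giving pseudo-frequency
#' `fs * omega0 / (2 pi scale)`.
#'
#' @param window_len window length in samples.
#' @param n_scales number of integer scales.
#' @param omega0 Morlet center angular frequency.
#' @return Complex matrix of dim `(n_scales * window_len) x window_len`;
#'   row `(s-1)*window_len + b` holds scale `s`, shift `b`.
#' @keywords internal
morlet_matrix <- function(window_len = 100L, n_scales = 50L, omega0 = 6) {
  k <- seq_len(window_len) - 1
  rows <- vector("list", n_scales)
  for (a in seq_len(n_scales)) {
    # psi*((k - b)/a) / sqrt(a) for every shift b
    M <- outer(k, k, function(b, kk) {
      t <- (kk - b) / a
      pi^(-1 / 4) * exp(-1i * omega0 * t) * exp(-t^2 / 2) / sqrt(a)
    })
    rows[[a]] <- M
  }
  do.call(rbind, rows)
}

#' Pseudo-frequencies (Hz) of the Morlet scales
#' @param n_scales number of integer scales.
#' @param fs sampling rate in Hz.
#' @param omega0 Morlet center angular frequency.
#' @return Numeric vector, one frequency per scale.
#' @export
scale_frequencies <- function(n_scales = 50L, fs = 1000, omega0 = 6) {
  fs * omega0 / (2 * pi * seq_len(n_scales))
}

#' CWT scalogram of one sample window
#'
#' Continuous wavelet transform magnitude of a short window at integer
#' scales: row `s` is scale `s`, column `t` the time offset within the
#' window.
#'
#' @param window numeric vector of exactly `window_len` samples.
#' @param n_scales number of scales (>= 1).
#' @param window_len expected window length.
#' @param wavelet_matrix optional precomputed [morlet_matrix()] (reused
#'   across windows for speed).
#' @return `n_scales x window_len` matrix of coefficient magnitudes.
#' @export
cwt_scalogram <- function(window, n_scales = 50L, window_len = 100L,
                          wavelet_matrix = NULL) {
  if (length(window) != window_len) {
    stop(sprintf("window must have exactly %d samples", window_len),
         call. = FALSE)
  }
  if (n_scales < 1) stop("n_scales must be >= 1", call. = FALSE)
  if (is.null(wavelet_matrix)) {
    wavelet_matrix <- morlet_matrix(window_len, n_scales)
  }
  matrix(Mod(wavelet_matrix %*% window), nrow = n_scales, byrow = TRUE)
}

#' Sliding-window two-channel spectrum-image sequence
#'
#' For every window position `n` (samples `n - window + 1, ..., n`, step 1),
#' computes the CWT scalogram of each named channel, stacks channel 1 above
#' channel 2 (giving `2 n_scales x window` images; 100 x 100 with defaults),
#' and min-max normalizes with extrema from the training split (computed
#' from this sequence when not supplied, and returned for freezing).
#'
#' @param emg `channels x samples` matrix with named rows.
#' @param channels pair of channel names to merge (default LGS and SOL).
#' @param window window length in samples.
#' @param step window step in samples.
#' @param n_scales scales per channel.
#' @param norm_extrema optional `c(min, max)` frozen from the training split.
#' @return `(2 n_scales) x window x n_images` array with attributes
#'   `norm_extrema` and `end_sample` (the window end positions);
#'   `n_images = floor((samples - window) / step) + 1`.
#' @export
spectrum_image_sequence <- function(emg, channels = c("LGS", "SOL"),
                                    window = 100L, step = 1L,
                                    n_scales = 50L, norm_extrema = NULL) {
  if (!is.matrix(emg) || is.null(rownames(emg))) {
    stop("emg must be a matrix with named channel rows", call. = FALSE)
  }
  missing_ch <- setdiff(channels, rownames(emg))
  if (length(missing_ch)) {
    stop(sprintf("unknown sEMG channel(s): %s",
                 paste(missing_ch, collapse = ", ")), call. = FALSE)
  }
  L <- ncol(emg)
  if (L < window) stop("trace shorter than one window", call. = FALSE)
  ends <- seq.int(window, L, by = step)
  A <- morlet_matrix(window, n_scales)
  # all windows of a channel as columns -> one matrix product per channel
  win_mat <- function(x) {
    vapply(ends, function(n) x[(n - window + 1):n], numeric(window))
  }
  mags <- lapply(channels, function(ch) {
    S <- Mod(A %*% win_mat(emg[ch, ]))
    array(S, dim = c(window, n_scales, length(ends)))  # (shift, scale, win)
  })
  out <- array(0, dim = c(2L * n_scales, window, length(ends)))
  for (t in seq_along(ends)) {
    top <- t(mags[[1]][, , t])     # scale x shift
    bot <- t(mags[[2]][, , t])
    out[, , t] <- rbind(top, bot)
  }
  if (is.null(norm_extrema)) norm_extrema <- range(out)
  span <- diff(norm_extrema)
  if (span > 0) out <- (out - norm_extrema[1]) / span
  attr(out, "norm_extrema") <- norm_extrema
  attr(out, "end_sample") <- ends
  out
}
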