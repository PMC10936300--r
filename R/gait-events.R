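#' Construct a sampled force trace
#'
#' @param values force samples in N.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in s.
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(values, fs, t0 = 0) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (!all(is.finite(values))) stop("force values must be finite", call. = FALSE)
  structure(list(values = as.numeric(values), fs = fs, t0 = t0),
            class = "force_trace")
}

#' Detect stance phases from vertical GRF by body-weight thresholding
#'
#' Heel-strike is an upward crossing and toe-off the subsequent downward
#' crossing of the 5% body-weight threshold (`0.05 * body_mass * 9.81` N);
#' super-threshold runs shorter than `min_stance` are discarded as chatter.
#'
#' @param grf a [force_trace()].
#' @param body_mass body mass in kg (> 0).
#' @param min_stance minimum stance duration in s (debounce).
#' @return A tibble with columns `heel_strike`, `toe_off` (1-based sample
#'   indices of the first and last super-threshold samples of each stance)
#'   and a `threshold_newtons` attribute. All-zero traces give zero rows.
#' @export
detect_stance <- function(grf, body_mass, min_stance = 0.2) {
  stopifnot(inherits(grf, "force_trace"))
  if (body_mass <= 0) stop("body_mass must be positive", call. = FALSE)
  thr <- 0.05 * body_mass * 9.81
  above <- grf$values >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= round(min_stance * grf$fs)
  ev <- tibble::tibble(heel_strike = starts[keep], toe_off = ends[keep])
  attr(ev, "threshold_newtons") <- thr
  ev
}

#' Segment synchronized streams into stance cycles
#'
#' Cuts every stream at each detected `[heel_strike, toe_off]` window. All
#' streams must share the analog timebase; image stacks are cut by frame
#' index (one frame per analog sample under trigger synchronization).
#'
#' @param events event tibble from [detect_stance()].
#' @param streams named list; each element is a numeric vector (per-sample
#'   trace), a `channels x samples` matrix, or an `H x W x frames` array.
#' @param speed optional walking speed annotation in m/s.
#' @return List of stance-cycle records (`speed`, `cycle_id`, `window`, plus
#'   one segmented entry per stream).
#' @export
segment_stance_cycles <- function(events, streams, speed = NA_real_) {
  stream_len <- function(s) {
    if (is.array(s) && length(dim(s)) == 3) dim(s)[3]
    else if (is.matrix(s)) ncol(s)
    else length(s)
  }
  lapply(seq_len(nrow(events)), function(k) {
    hs <- events$heel_strike[k]
    to <- events$toe_off[k]
    segs <- lapply(names(streams), function(nm) {
      s <- streams[[nm]]
      if (stream_len(s) < to) {
        stop(sprintf("stream '%s' is shorter than stance window [%d, %d]",
                     nm, hs, to), call. = FALSE)
      }
      if (is.array(s) && length(dim(s)) == 3) s[, , hs:to, drop = FALSE]
      else if (is.matrix(s)) s[, hs:to, drop = FALSE]
      else s[hs:to]
    })
    names(segs) <- names(streams)
    c(list(speed = speed, cycle_id = k, window = c(hs, to)), segs)
  })
}

#' Resample a stance-cycle trace onto a percent-stance grid
#'
#' Linear-interpolation resampling onto `n_points` equally spaced values of
#' percent stance (0% at heel-strike, 100% at toe-off); the endpoints are
#' preserved exactly.
#'
#' @param cycle_trace numeric trace over one stance (length >= 2).
#' @param n_points output grid size (>= 2; 101 by convention).
#' @return Numeric vector of length `n_points`.
#' @export
normalize_stance_percent <- function(cycle_trace, n_points = 101L) {
  if (length(cycle_trace) < 2) {
    stop("cycle_trace must have at least 2 samples", call. = FALSE)
  }
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  pct_in <- seq(0, 100, length.out = length(cycle_trace))
  pct_out <- seq(0, 100, length.out = n_points)
  out <- stats::approx(pct_in, cycle_trace, xout = pct_out)$y
  out[1] <- cycle_trace[1]
  out[n_points] <- cycle_trace[length(cycle_trace)]
  out
}
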