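# Sensor-stream preprocessing: gap interpolation onto the nominal 60 Hz
# grid, zero-phase low-pass filtering, and event-anchored window extraction.

#' Interpolate missing sensor values onto a uniform grid
#'
#' Rebuilds the stream on a uniform `1/fs` grid spanning the recorded time
#' range. Interior gaps (missing frames or NA channel values) are filled by
#' per-channel linear interpolation; values before the first or after the
#' last valid sample are extended with the nearest valid value. The result
#' has no missing values and is idempotent.
#'
#' @param sensor sensor data frame (`t` plus the nine inertial channels).
#' @param fs nominal sampling rate, Hz.
#' @return Gap-free sensor data frame on the uniform grid.
#' @export
interpolate_missing <- function(sensor, fs = 60) {
  stopifnot(nrow(sensor) >= 2)
  t0 <- min(sensor$t); t1 <- max(sensor$t)
  grid <- seq(t0, t0 + round((t1 - t0) * fs) / fs, by = 1 / fs)
  out <- data.frame(t = grid)
  for (ch in SENSOR_CHANNELS) {
    v <- sensor[[ch]]
    ok <- is.finite(v)
    if (sum(ok) < 2)
      stopf("channel %s has fewer than 2 valid frames; cannot interpolate", ch)
    out[[ch]] <- stats::approx(sensor$t[ok], v[ok], xout = grid,
                               method = "linear", rule = 2,
                               ties = "ordered")$y
  }
  out
}

# --- zero-phase IIR filtering ------------------------------------------------
# signal::butter supplies the coefficients; the forward-backward pass below
# uses odd-reflection padding and steady-state initial conditions so that a
# constant input is reproduced exactly and edge transients do not leak into
# the retained samples.

# Causal IIR pass with steady-state warm-up: the signal is prepended with a
# constant run of its first value long enough for the filter state to reach
# steady state, so a constant input is reproduced exactly (DC gain 1) and
# the start transient never reaches the retained samples.
WARMUP <- 150L

lfilter_warm <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(x[1], WARMUP + nb - 1), x)
  v <- stats::filter(xp, b / a[1], method = "convolution", sides = 1)
  v[seq_len(nb - 1)] <- 0
  y <- stats::filter(as.numeric(v), -a[-1] / a[1], method = "recursive")
  as.numeric(y)[WARMUP + nb - 1 + seq_along(x)]
}

filtfilt_refl <- function(b, a, x) {
  n <- max(length(a), length(b))
  padlen <- 3 * (n - 1)
  if (length(x) <= padlen)
    stopf("stream too short to filter: need more than %d frames, got %d",
          padlen, length(x))
  # odd reflection at both ends keeps slopes continuous across the joins
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)])
  y <- lfilter_warm(b, a, ext)
  y <- rev(lfilter_warm(b, a, rev(y)))
  y[(padlen + 1):(padlen + length(x))]
}

#' Zero-phase low-pass filter for sensor streams
#'
#' Butterworth low-pass (default 4th order, 20 Hz cutoff at 60 Hz sampling)
#' applied forward and backward to every inertial channel, so the net phase
#' is zero and timestamps stay aligned with the touch stream. The stream
#' must be gap-free and uniform (see [interpolate_missing()]).
#'
#' @param sensor gap-free uniform sensor data frame.
#' @param cutoff cutoff frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param order filter order.
#' @return Filtered sensor data frame; length and timestamps unchanged.
#' @export
lowpass <- function(sensor, cutoff = 20, fs = 60, order = 4) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  out <- sensor
  for (ch in SENSOR_CHANNELS)
    out[[ch]] <- filtfilt_refl(bf$b, bf$a, sensor[[ch]])
  out
}

#' Event-anchored sensor windows
#'
#' Splits the stream around an input event at `anchor_t` into the three
#' windows the feature set is built from: `pre` (the 10 frames immediately
#' before the anchor), `during` (the frame average over a one-frame-wide
#' interval centered on the anchor), and `post` (the 10 frames immediately
#' after). Events too close to a stream edge are padded by repeating the
#' terminal frame; the padding counts are returned so callers can log them.
#'
#' @param sensor gap-free uniform sensor data frame.
#' @param anchor_t input-event time, seconds.
#' @param n_frames frames per side (default 10).
#' @param fs sampling rate, Hz.
#' @return An `event_windows` list: `pre` and `post` (`n_frames` x 9
#'   matrices), `during` (length-9 named vector), `pad_pre`, `pad_post`.
#' @export
extract_windows <- function(sensor, anchor_t, n_frames = 10, fs = 60) {
  if (nrow(sensor) == 0) stopf("empty sensor stream")
  m <- as.matrix(sensor[, SENSOR_CHANNELS, drop = FALSE])
  half <- 1 / (2 * fs)
  pre_idx <- which(sensor$t < anchor_t)
  post_idx <- which(sensor$t > anchor_t)
  take <- function(idx, from_end) {
    pad <- max(0, n_frames - length(idx))
    if (length(idx) == 0) {
      # no frames on this side at all: repeat the nearest stream edge
      edge <- if (from_end) 1L else nrow(sensor)
      sel <- rep(edge, n_frames)
    } else {
      sel <- if (from_end) idx[max(1, length(idx) - n_frames + 1):length(idx)]
             else idx[1:min(n_frames, length(idx))]
      if (pad > 0) sel <- if (from_end) c(rep(sel[1], pad), sel)
                          else c(sel, rep(sel[length(sel)], pad))
    }
    list(m = m[sel, , drop = FALSE], pad = pad)
  }
  pre <- take(pre_idx, from_end = TRUE)
  post <- take(post_idx, from_end = FALSE)
  dur_idx <- which(sensor$t >= anchor_t - half & sensor$t <= anchor_t + half)
  if (length(dur_idx) == 0) dur_idx <- which.min(abs(sensor$t - anchor_t))
  during <- colMeans(m[dur_idx, , drop = FALSE])
  structure(list(pre = pre$m, during = during, post = post$m,
                 pad_pre = pre$pad, pad_post = post$pad),
            class = "event_windows")
}
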