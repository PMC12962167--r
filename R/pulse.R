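#' Construct a pulse trace
#'
#' A pulse trace holds a sampled reference pulse waveform (blood volume pulse
#' from a PPG sensor, or any cardiac proxy signal) together with its sampling
#' rate. It is the source of ground-truth heartbeat peaks for label
#' construction.
#'
#' @param amplitude Numeric vector of signal samples (length >= 2, all finite).
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start-time offset in seconds (default 0).
#' @param units Free-text amplitude units, kept as metadata.
#'
#' @return A tibble of class `pulse_trace` with columns `time_s` and
#'   `amplitude`, carrying `fs`, `t0` and `units` as attributes.
#' @export
#' @examples
#' p <- pulse_trace(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 50)), fs = 50)
#' pulse_fs(p)
pulse_trace <- function(amplitude, fs, t0 = 0, units = "a.u.") {
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop_invalid("`fs` must be a single positive sampling rate in Hz")
  }
  amplitude <- as.numeric(amplitude)
  if (length(amplitude) < 2) stop_invalid("a pulse trace needs at least 2 samples")
  if (!all(is.finite(amplitude))) stop_invalid("pulse trace contains non-finite samples")
  out <- tibble(
    time_s = t0 + (seq_along(amplitude) - 1) / fs,
    amplitude = amplitude
  )
  attr(out, "fs") <- fs
  attr(out, "t0") <- t0
  attr(out, "units") <- units
  class(out) <- c("pulse_trace", class(out))
  out
}

#' @rdname pulse_trace
#' @param trace A `pulse_trace`.
#' @export
pulse_fs <- function(trace) attr(trace, "fs")

#' Sequence of heartbeat peak indices
#'
#' Holds strictly ascending 0-based peak indices on a sampled axis (signal
#' samples or video frames) plus the rate of that axis. The largest
#' consecutive difference (`d_max`) parameterises the cosine decay outside the
#' first/last peak in [hbp_from_peaks()].
#'
#' @param index Integer-ish vector of strictly ascending 0-based indices.
#' @param fs Rate of the indexed axis in Hz (samples or frames per second).
#'
#' @return A tibble of class `peak_seq` with column `index`; `fs` is carried
#'   as an attribute.
#' @export
peak_seq <- function(index, fs) {
  index <- as.integer(round(index))
  if (length(index) && any(diff(index) <= 0)) {
    stop_invalid("peak indices must be strictly ascending")
  }
  if (length(index) && any(index < 0)) stop_invalid("peak indices must be non-negative")
  if (!is.numeric(fs) || fs <= 0) stop_invalid("`fs` must be positive")
  out <- tibble(index = index)
  attr(out, "fs") <- fs
  class(out) <- c("peak_seq", class(out))
  out
}

#' @rdname peak_seq
#' @param peaks A `peak_seq`.
#' @export
peak_d_max <- function(peaks) {
  if (nrow(peaks) < 2) return(NA_real_)
  max(diff(peaks$index))
}

#' Band-pass filter a pulse trace to the cardiac band
#'
#' Applies a zero-phase (forward-backward) order-4 Butterworth band-pass so
#' that peak positions are not shifted in time. The default 0.7--3.0 Hz band
#' corresponds to 42--180 beats per minute.
#'
#' @param trace A [pulse_trace()].
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz < fs / 2`.
#'
#' @return A filtered `pulse_trace` of the same length and sampling rate.
#' @export
bandpass_pulse <- function(trace, low_hz = 0.7, high_hz = 3.0) {
  fs <- pulse_fs(trace)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop_invalid(
      "band [%g, %g] Hz must satisfy 0 < low < high < fs/2 = %g",
      low_hz, high_hz, fs / 2
    )
  }
  # order-2 prototype -> order-4 band-pass; filtfilt makes it zero-phase
  bf <- signal::butter(2, c(low_hz, high_hz) / (fs / 2), type = "pass")
  filtered <- signal::filtfilt(bf, trace$amplitude)
  pulse_trace(filtered, fs = fs, t0 = attr(trace, "t0"), units = attr(trace, "units"))
}

#' Resample a pulse trace to a fixed length and remove its mean
#'
#' Linearly interpolates the trace onto `n_out` equally spaced points spanning
#' its duration, then subtracts the mean (optionally also dividing by the
#' standard deviation).
#'
#' @param trace A [pulse_trace()].
#' @param n_out Output length (>= 2); typically the clip length `T`.
#' @param scale If `TRUE`, also divide by the standard deviation. Default
#'   `FALSE` (plain mean normalisation).
#'
#' @return Numeric vector of length `n_out` with zero mean.
#' @export
resample_normalize <- function(trace, n_out, scale = FALSE) {
  if (!is.numeric(n_out) || length(n_out) != 1 || n_out < 2) {
    stop_invalid("`n_out` must be a single integer >= 2")
  }
  n_out <- as.integer(n_out)
  y <- approx(trace$time_s, trace$amplitude, n = n_out)$y
  y <- y - mean(y)
  if (scale) {
    s <- sd(y)
    if (s > 0) y <- y / s
  }
  y
}

#' Detect heartbeat peaks in a sampled signal
#'
#' Finds strict local maxima separated by at least the minimum inter-beat
#' distance implied by `max_hr_bpm` (`fs * 60 / max_hr_bpm` samples). When two
#' candidate maxima fall inside one exclusion window the larger amplitude
#' wins; amplitude ties keep the earlier index. The result is deterministic.
#'
#' @param signal Numeric vector (length >= 3) or a [pulse_trace()].
#' @param fs Sampling rate of `signal` in Hz (taken from the trace when a
#'   `pulse_trace` is given).
#' @param min_hr_bpm,max_hr_bpm Physiological heart-rate band; `max_hr_bpm`
#'   sets the exclusion distance, `min_hr_bpm` is kept as metadata for
#'   downstream validation.
#'
#' @return A [peak_seq()] of 0-based sample indices (possibly empty).
#' @export
detect_peaks <- function(signal, fs = NULL, min_hr_bpm = 40, max_hr_bpm = 180) {
  if (inherits(signal, "pulse_trace")) {
    fs <- pulse_fs(signal)
    signal <- signal$amplitude
  }
  if (is.null(fs)) stop_invalid("`fs` is required when `signal` is a plain vector")
  if (length(signal) < 3) stop_invalid("signal too short for peak detection (need >= 3 samples)")
  if (!(min_hr_bpm > 0 && min_hr_bpm < max_hr_bpm)) {
    stop_invalid("need 0 < min_hr_bpm < max_hr_bpm")
  }
  cand <- local_maxima(signal)            # 0-based
  if (!length(cand)) return(peak_seq(integer(0), fs))
  min_dist <- fs * 60 / max_hr_bpm
  amp <- signal[cand + 1]
  # greedy selection: amplitude descending, earlier index on ties
  ord <- order(-amp, cand)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - cand[i]) >= min_dist)) {
      kept <- c(kept, cand[i])
    }
  }
  peak_seq(sort(kept), fs)
}

#' Spectral heart-rate estimate from a pulse trace
#'
#' Estimates heart rate as 60 times the frequency of maximal spectral power
#' inside the cardiac band, using an averaged (Welch) periodogram with
#' 10-second Hann-windowed segments at 50% overlap when the trace is long
#' enough, else a single periodogram.
#'
#' @param trace A [pulse_trace()] of duration >= 5 s.
#' @param low_hz,high_hz Search band in Hz (default 0.7--3.0).
#'
#' @return Heart rate in beats per minute.
#' @export
psd_hr <- function(trace, low_hz = 0.7, high_hz = 3.0) {
  fs <- pulse_fs(trace)
  x <- trace$amplitude
  dur <- (length(x) - 1) / fs
  if (dur < 5) {
    stop_invalid("trace duration %.2f s too short for an in-band spectral estimate (need >= 5 s)", dur)
  }
  seg_len <- round(10 * fs)
  if (length(x) >= 2 * seg_len) {
    starts <- seq(1, length(x) - seg_len + 1, by = max(1L, seg_len %/% 2))
  } else {
    seg_len <- length(x)
    starts <- 1L
  }
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  freqs <- (seq_len(seg_len) - 1) * fs / seg_len
  power <- rep(0, seg_len)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * win
    power <- power + Mod(fft(seg))^2
  }
  in_band <- which(freqs >= low_hz & freqs <= high_hz)
  if (!length(in_band)) {
    stop_invalid("no spectral bin inside [%g, %g] Hz at resolution %g Hz", low_hz, high_hz, fs / seg_len)
  }
  60 * freqs[in_band[which.max(power[in_band])]]
}

#' Discard peaks whose inter-beat interval deviates from the median
#'
#' Motion artifacts in reference pulse recordings produce spurious or missing
#' peaks whose inter-beat intervals (IBIs) deviate strongly from the running
#' rhythm. Starting from the median of the current intervals, the filter
#' walks the sequence keeping a register of the last retained peak and drops
#' any peak terminating an interval whose relative deviation from the median
#' exceeds `rel_tol`; the pass is repeated until the peak set is stable, which
#' makes the operation idempotent.
#'
#' @param peaks A [peak_seq()] with >= 3 peaks (shorter inputs are returned
#'   unchanged with a warning).
#' @param rel_tol Maximum allowed relative deviation from the median interval
#'   (default 0.20, i.e. the 20% rule).
#'
#' @return A filtered `peak_seq`.
#' @export
filter_peaks_ibi <- function(peaks, rel_tol = 0.20) {
  if (nrow(peaks) < 3) {
    warn("fewer than 3 peaks; interval filter not applied")
    return(peaks)
  }
  idx <- peaks$index
  repeat {
    iv <- diff(idx)
    med <- median(iv)
    if (med <= 0) break
    keep <- idx[1]
    last <- idx[1]
    for (p in idx[-1]) {
      if (abs((p - last) - med) / med <= rel_tol) {
        keep <- c(keep, p)
        last <- p
      }
    }
    if (length(keep) == length(idx)) break
    idx <- keep
    if (length(idx) < 3) break
  }
  peak_seq(idx, attr(peaks, "fs"))
}

#' Cross-check peak-derived heart rate against the spectral estimate
#'
#' Compares the heart rate implied by the mean inter-beat interval with the
#' power-spectral-density estimate from the same trace. Segments whose two
#' estimates disagree by more than `rel_tol` (relative to the spectral value)
#' are flagged for exclusion from training labels.
#'
#' @param peaks A [peak_seq()] detected on `trace` (>= 2 peaks).
#' @param trace The underlying [pulse_trace()].
#' @param rel_tol Maximum tolerated relative difference (default 0.20).
#'
#' @return A one-row tibble: `pass`, `hr_from_peaks`, `hr_from_psd`,
#'   `rel_diff`.
#' @export
validate_peaks_psd <- function(peaks, trace, rel_tol = 0.20) {
  if (nrow(peaks) < 2) stop_invalid("need >= 2 peaks to compute an interval heart rate")
  fs <- attr(peaks, "fs")
  hr_peaks <- 60 * fs / mean(diff(peaks$index))
  hr_psd <- psd_hr(trace)
  rel <- abs(hr_peaks - hr_psd) / hr_psd
  tibble(
    pass = rel <= rel_tol,
    hr_from_peaks = hr_peaks,
    hr_from_psd = hr_psd,
    rel_diff = rel
  )
}

#' Heartbeat-probability map from a peak sequence
#'
#' Converts discrete heartbeat peaks into a smooth per-frame heartbeat
#' probability (HBP) sequence: a cosine kernel decays from exactly 1 at each
#' peak to 0 at inter-peak midpoints, so peak responses are smooth rather
#' than isolated impulses. Writing `P0`/`PT` for the first/last peak,
#' `PB(x)`/`PF(x)` for the peaks bracketing frame `x` and `Dmax` for the
#' largest inter-peak interval, the map is
#' \deqn{HBP(x) = 1/2 + 1/2 \cos(2\pi (x + Dmax - P0)/Dmax)}{HBP(x) = 1/2 + 1/2 cos(2pi (x + Dmax - P0)/Dmax)}
#' before `P0`,
#' \deqn{1/2 + 1/2 \cos(2\pi (x - PB(x))/(PF(x) - PB(x)))}{1/2 + 1/2 cos(2pi (x - PB)/(PF - PB))}
#' between peaks, and
#' \deqn{1/2 + 1/2 \cos(2\pi (x - PT)/Dmax)}{1/2 + 1/2 cos(2pi (x - PT)/Dmax)}
#' after `PT`. Frames are 0-based; the mid branch covers `P0 <= x <= PT`.
#'
#' @param peaks A [peak_seq()] with >= 2 peaks, all indices inside `[0, n_frames)`.
#' @param n_frames Temporal length `T` of the map, in frames.
#' @param fps Frames per second of the map axis (defaults to the peak axis rate).
#'
#' @return A tibble of class `hbp_map` with columns `frame_index`
#'   (0-based) and `probability`, carrying `fps` as an attribute.
#' @export
#' @examples
#' m <- hbp_from_peaks(peak_seq(c(10, 30), fs = 30), n_frames = 40)
#' m$probability[c(11, 21, 31)] # 1 at peaks, 0 at the midpoint
hbp_from_peaks <- function(peaks, n_frames, fps = NULL) {
  if (nrow(peaks) < 2) stop_invalid("HBP construction needs >= 2 peaks (Dmax undefined)")
  pk <- peaks$index
  if (any(pk < 0) || any(pk >= n_frames)) {
    stop_invalid("peak indices must lie inside [0, %d)", n_frames)
  }
  fps <- fps %||% attr(peaks, "fs")
  d_max <- max(diff(pk))
  x <- 0:(n_frames - 1)
  theta <- numeric(n_frames)
  p0 <- pk[1]
  pt <- pk[length(pk)]

  pre <- x < p0
  theta[pre] <- 2 * pi * (x[pre] + d_max - p0) / d_max
  post <- x > pt
  theta[post] <- 2 * pi * (x[post] - pt) / d_max
  mid <- !pre & !post
  if (any(mid)) {
    xm <- x[mid]
    # bracket each frame: pb = latest peak <= x, pf = next peak
    seg <- findInterval(xm, pk, rightmost.closed = FALSE)
    seg[seg >= length(pk)] <- length(pk) - 1  # x == pt sits in the last segment
    pb <- pk[seg]
    pf <- pk[seg + 1]
    theta[mid] <- 2 * pi * (xm - pb) / (pf - pb)
  }
  values <- 0.5 + 0.5 * cos(theta)
  out <- tibble(frame_index = x, probability = clamp01(values))
  attr(out, "fps") <- fps
  class(out) <- c("hbp_map", class(out))
  out
}

#' @rdname hbp_from_peaks
#' @param map An `hbp_map` (or numeric probability vector).
#' @export
hbp_values <- function(map) {
  if (inherits(map, "hbp_map")) map$probability else as.numeric(map)
}

#' @rdname hbp_from_peaks
#' @param values Numeric vector of probabilities in `[0, 1]`.
#' @export
hbp_map <- function(values, fps) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    stop_invalid("HBP values must be finite probabilities in [0, 1]")
  }
  out <- tibble(frame_index = seq_along(values) - 1L, probability = values)
  attr(out, "fps") <- fps
  class(out) <- c("hbp_map", class(out))
  out
}
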