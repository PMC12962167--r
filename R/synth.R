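#' Specification of a synthetic rPPG recording
#'
#' Describes a ground-truthed synthetic facial-video recording: a skin-toned
#' region whose green channel (and, at half amplitude, red channel) is
#' modulated by a pulse waveform of known heart rate, with configurable
#' rigid-translation motion, slow multiplicative illumination drift and
#' sensor noise. The three motion levels emulate stationary / slow / fast
#' movement conditions; illumination drift emulates lighting changes.
#'
#' @param duration_s Recording duration in seconds.
#' @param fps Video frame rate.
#' @param height,width Frame size in pixels.
#' @param hr_bpm Heart-rate trajectory: a single value (constant), a length-2
#'   vector (linear ramp), or `"walk"` for a bounded random walk. All values
#'   must stay inside \[40, 180\] bpm.
#' @param pulse_amplitude Fractional green-channel modulation depth
#'   (physiological scale ~0.002--0.02; default 0.01).
#' @param base_color RGB skin tone in `[0, 1]`.
#' @param roi Optional region box `c(x, y, w, h)` (0-based); default: a
#'   centred box of half the frame size.
#' @param motion `"static"`, `"slow"` or `"fast"`, mapped to random-walk
#'   displacement scales of 0 / 0.5 / 2 px per frame.
#' @param illumination_drift Amplitude of the slow multiplicative gain drift
#'   (0 disables; ~0.02 is a weak drift, ~0.05 strong).
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param pulse_fs Sampling rate of the reference pulse trace in Hz.
#' @param seed Seed fixing all randomness of the recording.
#'
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration_s = 30, fps = 30, height = 32, width = 32,
                           hr_bpm = 60, pulse_amplitude = 0.01,
                           base_color = c(0.72, 0.52, 0.42), roi = NULL,
                           motion = c("static", "slow", "fast"),
                           illumination_drift = 0, noise_sd = 0,
                           pulse_fs = 50, seed = 1) {
  motion <- match.arg(motion)
  hr_num <- if (is.character(hr_bpm)) c(40, 180) else range(hr_bpm)
  if (any(hr_num < 40) || any(hr_num > 180)) {
    stop_invalid("heart-rate trajectory must stay inside [40, 180] bpm")
  }
  if (pulse_amplitude < 0) stop_invalid("`pulse_amplitude` must be >= 0")
  if (is.null(roi)) {
    roi <- c(width %/% 4, height %/% 4, width %/% 2, height %/% 2)
  }
  structure(
    list(duration_s = duration_s, fps = fps, height = as.integer(height),
         width = as.integer(width), hr_bpm = hr_bpm,
         pulse_amplitude = pulse_amplitude, base_color = base_color,
         roi = as.integer(roi), motion = motion,
         motion_scale = c(static = 0, slow = 0.5, fast = 2)[[motion]],
         illumination_drift = illumination_drift, noise_sd = noise_sd,
         pulse_fs = pulse_fs, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Instantaneous heart rate (bpm) at time t for a spec; for "walk" the
# trajectory is drawn per beat inside generate_pulse.
hr_at <- function(spec, t) {
  hr <- spec$hr_bpm
  if (length(hr) == 1 && is.numeric(hr)) return(rep(hr[1], length(t)))
  if (is.numeric(hr) && length(hr) == 2) {
    return(hr[1] + (hr[2] - hr[1]) * pmin(pmax(t / spec$duration_s, 0), 1))
  }
  stop_invalid("hr trajectory must be evaluated per beat for a random walk")
}

#' Generate a ground-truthed synthetic pulse trace
#'
#' Beat times integrate the heart-rate trajectory (the next beat follows
#' after `60 / bpm(t)` seconds); each beat is an asymmetric raised-cosine
#' template with a sharp systolic peak (rising flank 30% of the period,
#' decay 70%), giving one unambiguous maximum per beat. Gaussian noise of
#' the specified standard deviation is added. Fully reproducible under the
#' spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `trace` (a [pulse_trace()]), `peak_times` (seconds),
#'   `hr_bpm_per_s` (tibble of the instantaneous trajectory).
#' @export
generate_pulse <- function(spec) {
  with_local_seed(spec$seed + 1000L, {
    walk <- is.character(spec$hr_bpm)
    dur <- spec$duration_s
    bpm0 <- if (walk) runif(1, 55, 105) else hr_at(spec, 0)[1]
    beats <- numeric(0)
    bpms <- numeric(0)
    t <- -60 / bpm0  # one beat before time zero anchors the first period
    bpm <- bpm0
    while (t <= dur + 2) {
      beats <- c(beats, t)
      bpms <- c(bpms, bpm)
      t <- t + 60 / bpm
      bpm <- if (walk) min(180, max(40, bpm + rnorm(1, 0, 1.5))) else hr_at(spec, min(t, dur))[1]
    }
    n <- round(dur * spec$pulse_fs) + 1
    ts <- (seq_len(n) - 1) / spec$pulse_fs
    seg <- findInterval(ts, beats)
    seg[seg < 1] <- 1
    seg[seg >= length(beats)] <- length(beats) - 1
    t_prev <- beats[seg]
    t_next <- beats[seg + 1]
    u <- (ts - t_prev) / (t_next - t_prev)
    # peak at u = 0; decay over 70% of the period, rise over the final 30%
    v <- ifelse(u <= 0.7,
                0.5 + 0.5 * cos(pi * u / 0.7),
                0.5 + 0.5 * cos(pi * (1 - u) / 0.3))
    v <- v + rnorm(n, 0, spec$noise_sd)
    trace <- pulse_trace(v, fs = spec$pulse_fs)
    keep <- beats >= 0 & beats < dur
    list(
      trace = trace,
      peak_times = beats[keep],
      hr_bpm_per_s = tibble(
        time_s = 0:floor(dur),
        bpm = vapply(0:floor(dur), function(s) {
          i <- findInterval(s, beats)
          bpms[max(1, min(i, length(bpms)))]
        }, numeric(1))
      )
    )
  })
}

#' Render a synthetic rPPG video
#'
#' Each frame is a constant background with a skin-toned region of interest
#' whose green channel decreases by `pulse_amplitude` times the normalised
#' pulse value at that frame time (red at half amplitude): at systolic peaks
#' oxyhaemoglobin absorbs green light most strongly, so the green channel
#' attains its minima at the true beat times. Motion shifts the region by a
#' seeded integer random walk; illumination applies a slow multiplicative
#' gain drift; Gaussian pixel noise is added last and values are clamped to
#' `[0, 1]`. If motion pushes the region outside the frame it is clipped,
#' with a count recorded in the result.
#'
#' @param spec A [synthetic_spec()].
#' @param pulse Optional result of [generate_pulse()] (generated when
#'   missing).
#' @return A list of class `synthetic_recording`: `frames` (a
#'   [frame_seq()]), `pulse` (the trace), `peak_times`, `peak_frames`
#'   (0-based), `roi`, `hr_bpm_per_s`, `clipped_frames`, `spec`.
#' @export
render_video <- function(spec, pulse = NULL) {
  if (is.null(pulse)) pulse <- generate_pulse(spec)
  n_frames <- round(spec$duration_s * spec$fps)
  frame_t <- (seq_len(n_frames) - 1) / spec$fps
  p <- approx(pulse$trace$time_s, pulse$trace$amplitude, xout = frame_t, rule = 2)$y
  rng <- range(p)
  p_norm <- if (diff(rng) > 0) (p - rng[1]) / diff(rng) else p * 0

  with_local_seed(spec$seed + 2000L, {
    dx <- round(cumsum(rnorm(n_frames, 0, spec$motion_scale)))
    dy <- round(cumsum(rnorm(n_frames, 0, spec$motion_scale)))
    gain <- 1 + spec$illumination_drift * sin(2 * pi * frame_t / spec$duration_s)
    H <- spec$height; W <- spec$width
    bg <- 0.25
    frames <- array(bg, dim = c(n_frames, H, W, 3))
    clipped <- 0L
    for (t in seq_len(n_frames)) {
      col <- spec$base_color +
        c(-0.5, -1, 0) * spec$pulse_amplitude * p_norm[t]
      x0 <- spec$roi[1] + dx[t]; y0 <- spec$roi[2] + dy[t]
      x1 <- x0 + spec$roi[3] - 1; y1 <- y0 + spec$roi[4] - 1
      cx0 <- max(0, x0); cy0 <- max(0, y0)
      cx1 <- min(W - 1, x1); cy1 <- min(H - 1, y1)
      if (cx0 != x0 || cy0 != y0 || cx1 != x1 || cy1 != y1) clipped <- clipped + 1L
      if (cx0 <= cx1 && cy0 <= cy1) {
        for (ch in 1:3) frames[t, (cy0 + 1):(cy1 + 1), (cx0 + 1):(cx1 + 1), ch] <- col[ch]
      }
      frames[t, , , ] <- frames[t, , , ] * gain[t]
      if (spec$noise_sd > 0) {
        frames[t, , , ] <- frames[t, , , ] + rnorm(H * W * 3, 0, spec$noise_sd)
      }
    }
    frames <- clamp01(frames)
    structure(
      list(
        frames = frame_seq(frames, spec$fps),
        pulse = pulse$trace,
        peak_times = pulse$peak_times,
        peak_frames = {
          pf <- as.integer(round(pulse$peak_times * spec$fps))
          pf[pf >= 0 & pf < n_frames]
        },
        roi = spec$roi,
        hr_bpm_per_s = pulse$hr_bpm_per_s,
        clipped_frames = clipped,
        spec = spec
      ),
      class = "synthetic_recording"
    )
  })
}

#' Mean green-channel trace of a region of interest
#'
#' The classical rPPG observable: the spatial mean of the green channel
#' inside the face box, as a [pulse_trace()] sampled at the frame rate.
#' Negated relative to blood volume (green absorption dips at beats), so the
#' returned trace is sign-flipped to peak at beats.
#'
#' @param frames A [frame_seq()].
#' @param box Optional `c(x, y, w, h)` region (default: whole frame).
#' @return A [pulse_trace()] at the frame rate.
#' @export
green_channel_trace <- function(frames, box = NULL) {
  f <- if (is.null(box)) frames else crop_face_roi(frames, box = box)
  g <- apply(unclass(f)[, , , 2, drop = FALSE], 1, mean)
  pulse_trace(-g, fs = attr(frames, "fps"))
}

#' Build a labelled synthetic clip dataset
#'
#' For every specification: render the recording, crop to its known region
#' box (bypassing face detection), resize to the network input size, segment
#' into clips, and construct heartbeat-probability labels from the true peak
#' frames over the whole recording (then sliced per clip). Returns the clips
#' with labels and a manifest.
#'
#' @param specs List of [synthetic_spec()]s.
#' @param clip_len Clip length `T` in frames.
#' @param mode `"train"` (50% overlap) or `"test"` (no overlap).
#' @param size Network input size `c(height, width)`.
#'
#' @return A list of class `hbp_dataset`: `clips`, `labels`, `manifest`
#'   (tibble: clip, recording, start_frame, true_hr_bpm), `fps`,
#'   `recordings` (the rendered recordings).
#' @export
make_dataset <- function(specs, clip_len = 64, mode = c("train", "test"),
                         size = c(32, 32)) {
  mode <- match.arg(mode)
  all_clips <- list(); all_labels <- list(); rows <- list(); recs <- list()
  for (r in seq_along(specs)) {
    rec <- render_video(specs[[r]])
    recs[[r]] <- rec
    cropped <- crop_face_roi(rec$frames, box = rec$roi)
    resized <- resize_normalize(cropped, size[1], size[2])
    n_frames <- dim(resized)[1]
    pk <- rec$peak_frames[rec$peak_frames >= 0 & rec$peak_frames < n_frames]
    label_full <- hbp_from_peaks(peak_seq(pk, specs[[r]]$fps), n_frames)
    cs <- segment_clips(resized, clip_len, mode, labels = label_full)
    for (k in seq_along(cs$clips)) {
      all_clips[[length(all_clips) + 1]] <- cs$clips[[k]]
      all_labels[[length(all_labels) + 1]] <- cs$labels[[k]]
      s <- cs$start_frames[k]
      window_t <- c(s, s + clip_len - 1) / specs[[r]]$fps
      traj <- rec$hr_bpm_per_s
      in_win <- traj$time_s >= window_t[1] & traj$time_s <= window_t[2]
      rows[[length(rows) + 1]] <- tibble(
        clip = length(all_clips) - 1L,
        recording = r,
        start_frame = s,
        true_hr_bpm = mean(traj$bpm[if (any(in_win)) in_win else which.min(abs(traj$time_s - window_t[1]))])
      )
    }
  }
  structure(
    list(clips = all_clips, labels = all_labels,
         manifest = dplyr::bind_rows(rows),
         fps = specs[[1]]$fps, recordings = recs),
    class = "hbp_dataset"
  )
}

#' @export
length.hbp_dataset <- function(x) length(x$clips)

#' Dataset manifest
#' @param x An `hbp_dataset`.
#' @param ... Unused.
#' @export
tidy.hbp_dataset <- function(x, ...) x$manifest
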