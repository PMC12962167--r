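# Shared fixture builders (all fixtures are generated in code).

# Pure sinusoid pulse trace at a given cardiac frequency.
sine_trace <- function(freq_hz, fs, duration_s, noise_sd = 0, seed = 1) {
  t <- seq(0, duration_s, by = 1 / fs)
  x <- sin(2 * pi * freq_hz * t)
  if (noise_sd > 0) {
    x <- x + with_seed_local(seed, rnorm(length(t), 0, noise_sd))
  }
  pulse_trace(x, fs = fs)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Tiny network configuration: cheapest valid architecture for structural tests.
tiny_config <- function(t_len = 8, hw = 16) {
  net_config(t_len, hw, hw, stage_widths = c(2, 3, 4, 5),
             head_widths = c(2, 3, 4, 3, 1))
}

# Constant-colour frame sequence.
const_frames <- function(t = 4, h = 16, w = 16, value = 0.4, fps = 30) {
  frame_seq(array(value, dim = c(t, h, w, 3)), fps)
}

# Power of a signal near a frequency, via the discrete Fourier transform.
band_power <- function(x, fs, centre, half_width = 0.05) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  p <- Mod(fft(x - mean(x)))^2
  sum(p[freqs >= centre - half_width & freqs <= centre + half_width])
}
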