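test_that("band-pass filtering isolates the cardiac band without shifting peaks", {
  fs <- 50
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 1.2 * t) + sin(2 * pi * 0.1 * t)
  trace <- pulse_trace(x, fs = fs)
  filt <- bandpass_pulse(trace, 0.7, 3.0)

  expect_equal(nrow(filt), nrow(trace))
  expect_equal(pulse_fs(filt), fs)
  # out-of-band power reduced by >= 20 dB, in-band kept
  p_before <- band_power(trace$amplitude, fs, 0.1)
  p_after <- band_power(filt$amplitude, fs, 0.1)
  expect_lt(p_after / p_before, 10^(-20 / 10))
  expect_gt(band_power(filt$amplitude, fs, 1.2) / band_power(trace$amplitude, fs, 1.2), 0.8)

  # passband identity up to edge effects: peak positions unchanged within 1
  pure <- sine_trace(1.2, fs, 20)
  pf <- bandpass_pulse(pure, 0.7, 3.0)
  interior <- function(p) p[p > 2 * fs & p < 18 * fs]
  p0 <- interior(detect_peaks(pure)$index)
  p1 <- interior(detect_peaks(pf)$index)
  expect_equal(length(p0), length(p1))
  expect_true(all(abs(p0 - p1) <= 1))
})

test_that("band-pass rejects invalid bands", {
  trace <- sine_trace(1.2, 50, 10)
  expect_error(bandpass_pulse(trace, 2.0, 1.0), class = "hbpnet_invalid_parameter")
  expect_error(bandpass_pulse(trace, 0.7, 30), class = "hbpnet_invalid_parameter")
})

test_that("resampling interpolates linearly and removes the mean", {
  trace <- pulse_trace(c(0, 1, 2, 3), fs = 1)
  expect_equal(resample_normalize(trace, 7), seq(0, 3, by = 0.5) - 1.5)
  const <- pulse_trace(rep(2.5, 10), fs = 5)
  expect_equal(resample_normalize(const, 6), rep(0, 6))
  expect_equal(mean(resample_normalize(sine_trace(1, 30, 7), 160)), 0)
  expect_error(resample_normalize(trace, 1), class = "hbpnet_invalid_parameter")
})

test_that("peak detection finds cosine maxima exactly and respects the distance rule", {
  x <- cos(2 * pi * (0:299) / 30)
  pk <- detect_peaks(x, fs = 30)
  expect_equal(pk$index, seq(30, 270, by = 30))

  expect_equal(nrow(detect_peaks(seq_len(50), fs = 30)), 0)  # monotone ramp

  # two candidates 5 apart with minimum distance 10: higher amplitude wins
  y <- rep(0, 20)
  y[6] <- 1.0   # 0-based index 5
  y[11] <- 0.8  # 0-based index 10
  pk2 <- detect_peaks(y, fs = 30, max_hr_bpm = 180)  # min distance 30*60/180 = 10
  expect_equal(pk2$index, 5)
  # brute-force check: every retained pair is >= 10 apart on a noisy signal
  z <- with_seed_local(4, rnorm(300))
  pz <- detect_peaks(z, fs = 30, max_hr_bpm = 180)$index
  if (length(pz) > 1) expect_true(all(diff(pz) >= 10))

  expect_error(detect_peaks(c(1, 2), fs = 30), class = "hbpnet_invalid_parameter")
})

test_that("spectral heart rate hits a pure tone on an exact bin", {
  trace <- pulse_trace(sin(2 * pi * 1.2 * (0:1199) / 30), fs = 30)
  expect_equal(psd_hr(trace), 72)

  noisy <- pulse_trace(
    sin(2 * pi * 1.0 * (0:1199) / 30) + with_seed_local(2, rnorm(1200, 0, 0.1)),
    fs = 30
  )
  bin_bpm <- 60 * 30 / round(10 * 30)  # Welch segment resolution in bpm
  expect_lt(abs(psd_hr(noisy) - 60), bin_bpm + 1e-9)

  short <- pulse_trace(sin(2 * pi * (0:14) / 30), fs = 30)  # 0.5 s
  expect_error(psd_hr(short), class = "hbpnet_invalid_parameter")
})

test_that("interval filter drops intervals deviating >20% from the median", {
  # intervals 30,30,30,60,30 -> the 60 interval and the orphaned trailing peak go
  pk <- peak_seq(c(0, 30, 60, 90, 150, 180), fs = 30)
  expect_equal(filter_peaks_ibi(pk)$index, c(0, 30, 60, 90))

  even <- peak_seq(seq(0, 150, 30), fs = 30)
  expect_equal(filter_peaks_ibi(even)$index, even$index)

  mild <- peak_seq(cumsum(c(0, 30, 33, 27)), fs = 30)  # max deviation 10%
  expect_equal(filter_peaks_ibi(mild)$index, mild$index)

  expect_warning(out <- filter_peaks_ibi(peak_seq(c(0, 30), fs = 30)), "fewer than 3")
  expect_equal(out$index, c(0, 30))
})

test_that("interval filter is idempotent on pulse-like peak sets", {
  for (seed in 1:8) {
    iv <- with_seed_local(seed, round(30 + rnorm(20, 0, 3)))
    iv[with_seed_local(seed + 100, sample(20, 2))] <- c(60, 15)  # inject artifacts
    pk <- peak_seq(cumsum(c(10, iv)), fs = 30)
    once <- suppressWarnings(filter_peaks_ibi(pk))
    twice <- suppressWarnings(filter_peaks_ibi(once))
    expect_equal(twice$index, once$index)
  }
})

test_that("peak/PSD cross-check passes clean pulses and fails thinned ones", {
  trace <- sine_trace(1.2, 50, 30)  # 72 bpm
  pk <- detect_peaks(trace)
  res <- validate_peaks_psd(pk, trace)
  expect_true(res$pass)
  expect_equal(res$hr_from_peaks, 72, tolerance = 0.02)
  expect_equal(res$hr_from_psd, 72, tolerance = 0.02)

  thinned <- peak_seq(pk$index[seq(1, nrow(pk), by = 2)], fs = 50)
  expect_false(validate_peaks_psd(thinned, trace)$pass)

  expect_true(validate_peaks_psd(thinned, trace, rel_tol = 1.0)$pass)
})

test_that("HBP map evaluates the three cosine branches exactly", {
  m <- hbp_from_peaks(peak_seq(c(10, 30), fs = 30), 40)
  v <- m$probability
  expect_equal(v[10 + 1], 1)
  expect_equal(v[30 + 1], 1)
  expect_equal(v[20 + 1], 0)
  expect_equal(v[5 + 1], 0.5)   # pre-branch: cos(2*pi*15/20)
  expect_equal(v[35 + 1], 0.5)  # post-branch: cos(2*pi*5/20)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(nrow(m), 40)

  expect_error(hbp_from_peaks(peak_seq(10, fs = 30), 40), class = "hbpnet_invalid_parameter")
  expect_error(hbp_from_peaks(peak_seq(c(10, 50), fs = 30), 40), class = "hbpnet_invalid_parameter")
})

test_that("HBP map is periodic between equally spaced peaks", {
  pk <- peak_seq(seq(15, 285, by = 30), fs = 30)
  v <- hbp_from_peaks(pk, 300)$probability
  mid <- v[(15 + 1):(285 + 1)]
  expect_equal(mid[seq_len(length(mid) - 30)], mid[-seq_len(30)])
})

test_that("HBP branch boundaries are continuous at the discretisation scale", {
  for (seed in 1:6) {
    pk_idx <- sort(with_seed_local(seed, sample(5:95, 4)))
    if (min(diff(pk_idx)) < 3) next
    v <- hbp_from_peaks(peak_seq(pk_idx, fs = 30), 100)$probability
    max_step <- max(abs(diff(v)))
    p0 <- pk_idx[1]; pt <- pk_idx[4]
    if (p0 > 0) expect_lte(abs(v[p0 + 1] - v[p0]), max_step + 1e-12)
    if (pt < 99) expect_lte(abs(v[pt + 2] - v[pt + 1]), max_step + 1e-12)
  }
})

test_that("peak detection round-trips an HBP map built from equal spacing", {
  pk <- peak_seq(seq(15, 285, by = 30), fs = 30)
  v <- hbp_from_peaks(pk, 300)$probability
  expect_equal(detect_peaks(v, fs = 30)$index, pk$index)
})

test_that("band-pass plus spectral estimate recovers a known synthetic rate", {
  gen <- generate_pulse(synthetic_spec(duration_s = 30, hr_bpm = 72, seed = 5))
  hr <- psd_hr(bandpass_pulse(gen$trace))
  expect_lt(abs(hr - 72), 60 / 10 + 1e-9)  # within one Welch bin
})

test_that("pulse traces round-trip through CSV with JSON sidecar", {
  trace <- sine_trace(1.1, 40, 5)
  path <- file.path(withr::local_tempdir(), "pulse.csv")
  write_pulse_csv(trace, path)
  back <- read_pulse_csv(path)
  expect_equal(back$amplitude, trace$amplitude, tolerance = 1e-10)
  expect_equal(pulse_fs(back), 40)

  m <- hbp_from_peaks(peak_seq(c(10, 30), fs = 30), 40)
  hpath <- file.path(withr::local_tempdir(), "hbp.csv")
  write_hbp_csv(m, hpath)
  expect_equal(read_hbp_csv(hpath, 30)$probability, m$probability, tolerance = 1e-10)
})
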