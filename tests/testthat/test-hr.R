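# Probability curve with strict local maxima of chosen heights at chosen
# 0-based positions (baseline 0.05, small shoulders).
spiky_curve <- function(n, peaks, heights) {
  x <- rep(0.05, n)
  x[peaks + 1] <- heights
  x
}

test_that("Peak-Refine recovers exact rates from clean periodic maps", {
  cfg <- detection_config(confidence = 0.7, fps = 30, median_window = 1)
  for (spacing in seq(15, 45, by = 5)) {
    pk <- peak_seq(seq(spacing, 20 * spacing, by = spacing), fs = 30)
    v <- hbp_from_peaks(pk, 21 * spacing)$probability
    est <- peak_refine_hr(hbp_map(v, 30), cfg)
    expect_equal(est$bpm, 30 * 60 / spacing, tolerance = 1e-12)
    expect_equal(est$n_intervals, 19)
  }
})

test_that("the confidence register excludes intervals flanking low peaks", {
  # hand trace: peaks {10,40,70,95,125}, values {.9,.9,.5,.9,.9}
  v <- spiky_curve(140, c(10, 40, 70, 95, 125), c(0.9, 0.9, 0.5, 0.9, 0.9))
  cfg <- detection_config(confidence = 0.7, fps = 30, median_window = 1)
  est <- peak_refine_hr(hbp_map(v, 30), cfg)
  expect_equal(est$intervals[[1]], c(30, 30))
  expect_equal(est$bpm, 60)

  low <- spiky_curve(100, c(20, 50, 80), c(0.5, 0.5, 0.5))
  expect_error(peak_refine_hr(hbp_map(low, 30), cfg), class = "hbpnet_no_estimate")
})

test_that("sub-threshold spurious peaks never change the estimate", {
  cfg <- detection_config(confidence = 0.7, fps = 30, median_window = 1)
  true_peaks <- seq(20, 260, by = 30)
  base <- spiky_curve(300, true_peaks, rep(0.95, length(true_peaks)))
  ref <- peak_refine_hr(hbp_map(base, 30), cfg)
  for (seed in 1:10) {
    gaps <- setdiff(5:290, as.vector(outer(true_peaks, -2:2, `+`)))
    spots <- with_seed_local(seed, sample(gaps, 5))
    vals <- with_seed_local(seed + 10, runif(5, 0.1, 0.69))
    contaminated <- base
    contaminated[spots + 1] <- vals
    est <- peak_refine_hr(hbp_map(contaminated, 30), cfg)
    expect_equal(est$bpm, ref$bpm)
  }
})

test_that("raising the confidence never increases the appended interval count", {
  for (seed in 1:6) {
    pk <- sort(with_seed_local(seed, sample(seq(5, 290, by = 5), 12)))
    hts <- with_seed_local(seed + 20, runif(12, 0.3, 1))
    v <- spiky_curve(300, pk, hts)
    counts <- vapply(seq(0.3, 0.9, by = 0.1), function(th) {
      cfg <- detection_config(confidence = th, fps = 30, median_window = 1,
                              mad_multiplier = NA)
      est <- tryCatch(peak_refine_hr(hbp_map(v, 30), cfg),
                      hbpnet_no_estimate = function(e) NULL)
      if (is.null(est)) 0L else est$n_intervals
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("median filtering keeps intervals inside the input range", {
  for (seed in 1:5) {
    iv <- with_seed_local(seed, runif(11, 20, 40))
    filtered <- hbpnet:::median_filter_intervals(iv, 3)
    expect_true(all(filtered >= min(iv) & filtered <= max(iv)))
    expect_equal(hbpnet:::median_filter_intervals(iv, 1), iv)
  }
})

test_that("MAD outlier removal follows the 1.5x rule with a degenerate guard", {
  iv <- c(1.0, 1.03, 0.97, 1.0, 3.0)
  expect_equal(remove_outlier_ibis(iv), c(1.0, 1.03, 0.97, 1.0))
  expect_equal(remove_outlier_ibis(rep(0.8, 5)), rep(0.8, 5))  # MAD = 0
  expect_warning(out <- remove_outlier_ibis(c(1, 1)), "fewer than 3")
  expect_equal(out, c(1, 1))
})

test_that("metrics match hand arithmetic and the RMSE >= MAE ordering", {
  m <- compute_metrics(c(62, 58), c(60, 60))
  expect_equal(m$mae, 2)
  expect_equal(m$rmse, 2)

  ident <- compute_metrics(c(70, 80, 90), c(70, 80, 90))
  expect_equal(ident$mae, 0)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$pearson_r, 1)

  shift <- compute_metrics(c(70, 80, 90) + 5, c(70, 80, 90))
  expect_equal(shift$mae, 5)
  expect_equal(shift$pearson_r, 1)

  const <- compute_metrics(c(60, 60), c(60, 61))
  expect_false(const$r_defined)

  for (seed in 1:8) {
    a <- with_seed_local(seed, runif(10, 50, 110))
    b <- with_seed_local(seed + 30, runif(10, 50, 110))
    mm <- compute_metrics(a, b)
    expect_gte(mm$rmse, mm$mae)
    expect_gte(mm$mae, 0)
    expect_true(abs(mm$pearson_r) <= 1)
  }
  expect_error(compute_metrics(1:3, 1:4), class = "hbpnet_invalid_parameter")
})

test_that("grid search picks the MAE-minimising threshold with low-tie preference", {
  cfg <- detection_config(fps = 30, median_window = 1)
  # clean maps: every threshold gives identical (zero) MAE -> 0.6 by tie-break
  clean <- lapply(c(30, 25), function(s) {
    pk <- peak_seq(seq(s, 12 * s, by = s), fs = 30)
    hbp_from_peaks(pk, 13 * s)
  })
  th <- grid_search_confidence(clean, 60 * 30 / c(30, 25), cfg)
  expect_equal(as.numeric(th), 0.6)

  # spurious 0.65-valued peaks in some gaps corrupt only the 0.6 pass; at
  # >= 0.7 they clear the register, excluding just their flanking intervals
  mk <- function() {
    v <- spiky_curve(300, seq(20, 280, by = 30), rep(0.95, 9))
    v[c(35, 95, 155) + 1] <- 0.65
    hbp_map(v, 30)
  }
  th2 <- grid_search_confidence(list(mk(), mk()), c(60, 60), cfg)
  expect_gte(as.numeric(th2), 0.7)

  expect_error(grid_search_confidence(list(), numeric(0), cfg),
               class = "hbpnet_invalid_parameter")
})

test_that("grid search agrees with exhaustive evaluation on seeded synthetic sets", {
  base_cfg <- detection_config(fps = 30, median_window = 1)
  for (seed in 1:5) {
    preds <- list(); truth <- numeric(0)
    for (k in 1:4) {
      spacing <- with_seed_local(seed * 10 + k, sample(18:36, 1))
      pk <- peak_seq(seq(spacing, 10 * spacing, by = spacing), fs = 30)
      v <- hbp_from_peaks(pk, 11 * spacing)$probability
      n_noise <- with_seed_local(seed * 20 + k, sample(2:5, 1))
      spots <- with_seed_local(seed * 30 + k,
                               sample(setdiff(seq(5, 10 * spacing, by = 7), pk$index), n_noise))
      v[spots + 1] <- pmax(v[spots + 1], with_seed_local(seed * 40 + k, runif(n_noise, 0.55, 0.8)))
      preds[[k]] <- hbp_map(pmin(v, 1), 30)
      truth[k] <- 30 * 60 / spacing
    }
    got <- as.numeric(grid_search_confidence(preds, truth, base_cfg))
    # independent exhaustive evaluation over the four grid values
    maes <- vapply(base_cfg$grid, function(th) {
      cfg <- base_cfg; cfg$confidence <- th
      errs <- vapply(seq_along(preds), function(i) {
        est <- tryCatch(peak_refine_hr(preds[[i]], cfg),
                        hbpnet_no_estimate = function(e) NULL)
        if (is.null(est)) NA_real_ else abs(est$bpm - truth[i])
      }, numeric(1))
      if (any(is.finite(errs))) mean(errs, na.rm = TRUE) else Inf
    }, numeric(1))
    expect_equal(got, base_cfg$grid[which.min(maes)])
  }
})

test_that("recording-level estimation concatenates clips and can fall back to PSD", {
  pk <- peak_seq(seq(15, 585, by = 30), fs = 30)
  v <- hbp_from_peaks(pk, 600)$probability
  clips <- split(v, rep(1:5, each = 120))
  est <- recording_hr(clips, detection_config(confidence = 0.7, fps = 30))
  expect_equal(est$bpm, 60, tolerance = 1e-9)

  flatish <- lapply(1:3, function(i) {
    pmin(pmax(rep(0.4, 120) + sin(2 * pi * 1.5 * (1:120) / 30) * 0.05, 0), 1)
  })
  est2 <- recording_hr(flatish, detection_config(confidence = 0.99, fps = 30))
  expect_equal(est2$aggregate, "psd_fallback")
  expect_equal(est2$bpm, 90, tolerance = 6)
})
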