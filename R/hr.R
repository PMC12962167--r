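#' Detection configuration for Peak-Refine
#'
#' @param confidence Probability threshold in `[0, 1]` below which a detected
#'   peak clears the interval register (its flanking intervals are excluded).
#' @param grid Candidate thresholds for [grid_search_confidence()].
#' @param median_window Odd window for the running median filter over the
#'   interval list; 1 disables filtering.
#' @param aggregate `"mean"` (heart rate from the mean interval, the
#'   Peak-Refine default) or `"median"` (60 / median inter-beat interval,
#'   the inference-protocol variant).
#' @param mad_multiplier Remove intervals deviating more than this multiple
#'   of the median absolute deviation from the median; `NA` disables removal
#'   (default: enabled at 1.5 in `"median"` mode only).
#' @param fps Frames per second of the probability map axis.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(confidence = 0.7, grid = seq(0.6, 0.9, by = 0.1),
                             median_window = 3, aggregate = c("mean", "median"),
                             mad_multiplier = NULL, fps = 30) {
  aggregate <- match.arg(aggregate)
  if (confidence < 0 || confidence > 1 || any(grid < 0) || any(grid > 1)) {
    stop_invalid("confidence values must lie in [0, 1]")
  }
  if (median_window < 1 || median_window %% 2 == 0) {
    stop_invalid("`median_window` must be an odd integer >= 1")
  }
  if (is.null(mad_multiplier)) {
    mad_multiplier <- if (aggregate == "median") 1.5 else NA_real_
  }
  structure(
    list(confidence = confidence, grid = grid, median_window = as.integer(median_window),
         aggregate = aggregate, mad_multiplier = mad_multiplier, fps = fps),
    class = "detection_config"
  )
}

#' Heart rate from a heartbeat-probability map (Peak-Refine)
#'
#' Detects local maxima of the probability curve and walks them in order
#' with a last-confident-peak register: a peak at or below the confidence
#' threshold clears the register, excluding both intervals it touches; a
#' confident peak appends the interval since the registered peak (when one
#' is set) and then becomes the register. Spurious low-probability peaks
#' therefore cannot corrupt the interval list. The interval list is
#' median-filtered, optionally cleaned of outliers beyond
#' `mad_multiplier` x MAD from the median, and aggregated to beats per
#' minute.
#'
#' As printed, the reference pseudocode's first branch would capture every
#' confident peak and never append; the implementation uses the evidently
#' intended register semantics described above, which matches the
#' surrounding description of the method.
#'
#' @param hbp An [hbp_map()] or numeric probability vector.
#' @param config A [detection_config()].
#'
#' @return A one-row tibble of class `hr_estimate`: `bpm`, `n_intervals`,
#'   `threshold`, `aggregate`, `flagged` (TRUE when outside the 30--240 bpm
#'   sanity band), and `intervals` (list-column, frames).
#' @export
peak_refine_hr <- function(hbp, config = detection_config()) {
  values <- hbp_values(hbp)
  fps <- attr(hbp, "fps") %||% config$fps
  conf <- config$confidence
  peaks <- local_maxima(values)                     # 0-based
  intervals <- numeric(0)
  register <- NA_real_
  for (pk in peaks) {
    if (values[pk + 1] <= conf) {
      register <- NA_real_
    } else {
      if (!is.na(register)) intervals <- c(intervals, pk - register)
      register <- pk
    }
  }
  if (length(intervals) < 1) {
    stop_no_estimate(
      "fewer than 2 confident peaks (threshold %.2f): %d peaks detected, %d confident",
      conf, length(peaks), sum(values[peaks + 1] > conf)
    )
  }
  intervals <- median_filter_intervals(intervals, config$median_window)
  if (is.finite(config$mad_multiplier) && length(intervals) >= 3) {
    intervals <- mad_filter(intervals, config$mad_multiplier)
  }
  bpm <- if (config$aggregate == "mean") {
    fps / mean(intervals) * 60
  } else {
    60 / median(intervals / fps)
  }
  out <- tibble(
    bpm = bpm,
    n_intervals = length(intervals),
    threshold = conf,
    aggregate = config$aggregate,
    flagged = !(bpm >= 30 && bpm <= 240),
    intervals = list(intervals)
  )
  class(out) <- c("hr_estimate", class(out))
  out
}

median_filter_intervals <- function(iv, window) {
  if (window <= 1 || length(iv) < 2) return(iv)
  k <- min(window, if (length(iv) %% 2 == 0) length(iv) - 1 else length(iv))
  if (k < 3) return(iv)
  as.numeric(runmed(iv, k, endrule = "median"))
}

mad_filter <- function(iv, multiplier) {
  med <- median(iv)
  m <- mad(iv, constant = 1)
  if (m == 0) return(iv)  # degenerate: identical intervals, nothing to remove
  iv[abs(iv - med) <= multiplier * m]
}

#' Remove outlier inter-beat intervals
#'
#' Intervals whose absolute deviation from the median exceeds
#' `multiplier` x MAD (median absolute deviation, unscaled) are removed.
#' When the MAD is 0 the rule is degenerate and nothing is removed. Inputs
#' with fewer than 3 intervals are returned unchanged with a warning.
#'
#' @param intervals Numeric inter-beat intervals (seconds).
#' @param multiplier MAD multiplier (default 1.5).
#' @return Filtered interval vector.
#' @export
remove_outlier_ibis <- function(intervals, multiplier = 1.5) {
  if (length(intervals) < 3) {
    warn("fewer than 3 intervals; outlier removal not applied")
    return(intervals)
  }
  mad_filter(intervals, multiplier)
}

#' Select the confidence threshold by validation grid search
#'
#' Evaluates [peak_refine_hr()] at every grid value on a validation set with
#' reference heart rates and returns the threshold minimising the mean
#' absolute error; ties break toward the lower threshold. Recordings that
#' yield no estimate at a threshold are excluded from that threshold's MAE
#' with a logged count.
#'
#' @param predictions List of [hbp_map()]s (or numeric vectors).
#' @param true_hr Numeric reference heart rates (bpm), one per prediction.
#' @param config A [detection_config()] providing the grid and filters.
#'
#' @return The selected threshold (numeric scalar) with the full search
#'   table attached as attribute `"search"` (a tibble: threshold, mae,
#'   n_used, n_no_estimate).
#' @export
grid_search_confidence <- function(predictions, true_hr, config = detection_config()) {
  if (!length(predictions)) stop_invalid("empty validation set")
  if (length(predictions) != length(true_hr)) {
    stop_invalid("got %d predictions but %d reference heart rates",
                 length(predictions), length(true_hr))
  }
  rows <- lapply(config$grid, function(th) {
    cfg <- config
    cfg$confidence <- th
    errs <- vapply(seq_along(predictions), function(i) {
      est <- tryCatch(peak_refine_hr(predictions[[i]], cfg),
                      hbpnet_no_estimate = function(e) NULL)
      if (is.null(est)) NA_real_ else abs(est$bpm - true_hr[i])
    }, numeric(1))
    tibble(
      threshold = th,
      mae = if (any(is.finite(errs))) mean(errs, na.rm = TRUE) else NA_real_,
      n_used = sum(is.finite(errs)),
      n_no_estimate = sum(!is.finite(errs))
    )
  })
  search <- dplyr::bind_rows(rows)
  if (!any(is.finite(search$mae))) {
    stop_no_estimate("no threshold on the grid yields any heart-rate estimate")
  }
  best <- search$threshold[which.min(search$mae)]  # which.min takes the first (lowest) tie
  structure(best, search = search)
}

#' Heart-rate accuracy metrics
#'
#' Mean absolute error, root-mean-square error and Pearson correlation
#' between predicted and reference heart rates, computed over recordings.
#'
#' @param pred_hr,true_hr Equal-length numeric heart-rate vectors (bpm).
#' @return A one-row tibble: `mae`, `rmse`, `pearson_r`, `r_defined`, `n`.
#' @export
compute_metrics <- function(pred_hr, true_hr) {
  if (length(pred_hr) != length(true_hr)) {
    stop_invalid("prediction (%d) and reference (%d) lengths differ",
                 length(pred_hr), length(true_hr))
  }
  if (!length(pred_hr)) stop_invalid("empty input")
  err <- pred_hr - true_hr
  r_def <- length(pred_hr) >= 2 && sd(pred_hr) > 0 && sd(true_hr) > 0
  tibble(
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    pearson_r = if (r_def) cor(pred_hr, true_hr) else NA_real_,
    r_defined = r_def,
    n = length(pred_hr)
  )
}

#' Recording-level heart rate from clip-wise predictions
#'
#' Concatenates clip predictions (test-time clips are non-overlapping) and
#' runs Peak-Refine on the joined sequence; clip-boundary peaks are handled
#' by the same local-maximum rule on the concatenated curve. When no pair of
#' confident peaks exists, the function falls back to the spectral
#' (periodogram) estimate of the predicted probability curve, which is
#' periodic at the heart rate by construction.
#'
#' @param clip_predictions List of numeric per-clip probability vectors in
#'   temporal order.
#' @param config A [detection_config()].
#' @param psd_fallback Use the spectral fallback instead of failing, also
#'   when the interval estimate lands outside the 30--240 bpm sanity band
#'   (default `TRUE`).
#' @return A one-row `hr_estimate` tibble (the fallback sets
#'   `n_intervals = 0` and `threshold = NA`).
#' @export
recording_hr <- function(clip_predictions, config = detection_config(),
                         psd_fallback = TRUE) {
  joined <- unlist(lapply(clip_predictions, hbp_values))
  est <- tryCatch(
    peak_refine_hr(hbp_map(clamp01(joined), config$fps), config),
    hbpnet_no_estimate = function(e) if (psd_fallback) NULL else abort(conditionMessage(e), class = "hbpnet_no_estimate")
  )
  if (!is.null(est) && est$flagged && psd_fallback) est <- NULL
  if (!is.null(est)) return(est)
  bpm <- psd_hr(pulse_trace(joined - mean(joined), fs = config$fps))
  out <- tibble(
    bpm = bpm, n_intervals = 0L, threshold = NA_real_,
    aggregate = "psd_fallback", flagged = !(bpm >= 30 && bpm <= 240),
    intervals = list(numeric(0))
  )
  class(out) <- c("hr_estimate", class(out))
  out
}

#' Scatter plot of predicted versus reference heart rate
#'
#' @param pred_hr,true_hr Numeric heart rates (bpm).
#' @return A ggplot object with the identity line.
#' @export
plot_hr_scatter <- function(pred_hr, true_hr) {
  df <- tibble(true_hr = true_hr, pred_hr = pred_hr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true_hr, y = .data$pred_hr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reference HR (bpm)", y = "predicted HR (bpm)") +
    ggplot2::theme_minimal()
}
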