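#' Read and write pulse traces as CSV with a JSON sidecar
#'
#' The CSV holds columns `time_s` and `amplitude`; the sidecar
#' (`<path>.json`) records the sampling rate and units. When the sidecar is
#' missing on read, the sampling rate is inferred from the median time step.
#'
#' @param path CSV file path.
#' @return `read_pulse_csv()` returns a [pulse_trace()].
#' @export
read_pulse_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "amplitude") %in% names(df))) {
    stop_invalid("pulse CSV must have header columns time_s, amplitude")
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fs <- meta$fs
    units <- meta$units %||% "a.u."
  } else {
    fs <- 1 / median(diff(df$time_s))
    units <- "a.u."
  }
  pulse_trace(df$amplitude, fs = fs, t0 = df$time_s[1], units = units)
}

#' @rdname read_pulse_csv
#' @param trace A [pulse_trace()].
#' @export
write_pulse_csv <- function(trace, path) {
  readr::write_csv(as_tibble(trace)[, c("time_s", "amplitude")], path)
  jsonlite::write_json(
    list(fs = pulse_fs(trace), units = attr(trace, "units")),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read and write heartbeat-probability maps as CSV
#'
#' Columns `frame_index` (0-based) and `probability`.
#'
#' @param path CSV file path.
#' @param fps Frames per second to attach on read (default 30).
#' @return `read_hbp_csv()` returns an [hbp_map()].
#' @export
read_hbp_csv <- function(path, fps = 30) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("frame_index", "probability") %in% names(df))) {
    stop_invalid("HBP CSV must have header columns frame_index, probability")
  }
  hbp_map(df$probability[order(df$frame_index)], fps)
}

#' @rdname read_hbp_csv
#' @param map An [hbp_map()].
#' @export
write_hbp_csv <- function(map, path) {
  readr::write_csv(as_tibble(map)[, c("frame_index", "probability")], path)
  invisible(path)
}
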