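#' Stream filtering configuration
#'
#' @param median_window Odd window of the sliding median (default 5).
#' @param ma_window Window of the trailing moving average (default 5).
#' @param sampling_interval_s Sensor reading interval in seconds
#'   (default 0.7).
#' @return Object of class `stream_config`.
#' @export
stream_config <- function(median_window = 5, ma_window = 5,
                          sampling_interval_s = 0.7) {
  if (median_window < 1 || median_window %% 2 == 0) {
    stop("median_window must be a positive odd integer", call. = FALSE)
  }
  if (ma_window < 1) stop("ma_window must be >= 1", call. = FALSE)
  if (sampling_interval_s <= 0) {
    stop("sampling_interval_s must be positive", call. = FALSE)
  }
  structure(list(median_window = as.integer(median_window),
                 ma_window = as.integer(ma_window),
                 sampling_interval_s = sampling_interval_s),
            class = "stream_config")
}

#' Sliding median filter
#'
#' Length-preserving sliding median. Near the edges the window is
#' truncated symmetrically to the largest centered odd window that fits,
#' so the first and last samples pass through unchanged.
#'
#' @param series Numeric vector.
#' @param window Odd window length, at most `length(series)`.
#' @return Filtered vector, same length.
#' @export
#' @examples
#' median_filter(c(1, 9, 1), 3)  # 1 1 1 - the spike is removed
median_filter <- function(series, window) {
  n <- length(series)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window < 1 || window > n) {
    stop("window must lie in [1, length(series)]", call. = FALSE)
  }
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    stats::median(series[(i - h):(i + h)])
  }, numeric(1))
}

#' Trailing moving-average filter
#'
#' Length-preserving trailing mean: sample i is averaged over the
#' `window` most recent samples, truncated during warm-up, which keeps
#' the filter causal for a live stream.
#'
#' @param series Numeric vector.
#' @param window Window length, at most `length(series)`.
#' @return Filtered vector, same length.
#' @export
#' @examples
#' moving_average(c(0, 10), 2)  # 0 5
moving_average <- function(series, window) {
  n <- length(series)
  if (window < 1 || window > n) {
    stop("window must lie in [1, length(series)]", call. = FALSE)
  }
  window <- as.integer(window)
  cs <- cumsum(series)
  lag <- c(rep(0, window), cs[seq_len(n - window)])
  denom <- pmin(seq_len(n), window)
  (cs - lag) / denom
}

#' Dynamic SpO2 estimation over a frame stream
#'
#' Per frame: restrict to the model's spectral region, min-max
#' normalize, predict class weights and decode to a scalar SpO2 (raw);
#' then smooth with the median filter followed by the moving-average
#' filter (filtered). Timestamps are taken from the frames when present,
#' otherwise spaced by the configured sampling interval.
#'
#' @param model A fitted `oxi_cnn`.
#' @param frames Time-ordered list of `spectral_frame`s.
#' @param region Region the model was trained on (preset name or
#'   [region_spec()]).
#' @param cfg A [stream_config()].
#' @return data.frame with columns `timestamp`, `raw`, `filtered`.
#' @export
stream_estimate <- function(model, frames, region, cfg = stream_config()) {
  region <- region_spec(region)
  if (length(region$centers_nm) != model$input_length) {
    stop("region width ", length(region$centers_nm),
         " does not match the model input length ", model$input_length,
         call. = FALSE)
  }
  X <- t(vapply(frames, function(f) {
    fr <- select_region(f, region)
    suppressWarnings(normalize_spectrum(fr$dc))
  }, numeric(length(region$centers_nm))))
  raw <- predict(model, X, type = "spo2")
  filt <- moving_average(median_filter(raw, cfg$median_window), cfg$ma_window)
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (all(ts == 0) && length(ts) > 1) {
    ts <- (seq_along(ts) - 1) * cfg$sampling_interval_s
  }
  data.frame(timestamp = ts, raw = raw, filtered = filt)
}
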