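#' First derivative of a skin-temperature record
#'
#' Low-pass smooths the signal (zero-phase Butterworth, corner `smooth_hz`)
#' and differentiates by central finite differences; the two endpoint
#' samples are dropped. Exact for linear trends away from the filter's edge
#' transients.
#'
#' @param temp A `channel_recording`, at least 30 s long.
#' @param smooth_hz Smoothing corner frequency in Hz (default 0.1); `NULL`
#'   skips smoothing.
#' @return A `channel_recording` of kind `"temp_derivative"` in Celsius per
#'   second, two samples shorter than the input.
#' @export
estimate_derivative <- function(temp, smooth_hz = 0.1) {
  stopifnot(inherits(temp, "channel_recording"))
  if (duration(temp) < 30) stop("record must be at least 30 s long", call. = FALSE)
  x <- temp$values
  if (!is.null(smooth_hz)) {
    if (smooth_hz >= temp$fs / 2) stop("`smooth_hz` must be below Nyquist", call. = FALSE)
    bw <- signal::butter(4, smooth_hz / (temp$fs / 2), type = "low")
    x <- zp_filtfilt(bw, x, temp$fs, pad_s = 1.5 / smooth_hz, detrend = TRUE)
  }
  n <- length(x)
  d <- (x[3:n] - x[1:(n - 2)]) * temp$fs / 2
  channel_recording(d, temp$fs, "temp_derivative", t0 = temp$t0 + 1 / temp$fs)
}

#' Temperature (or temperature-derivative) phase features
#'
#' The seven per-phase summaries of a temperature-like series: initial
#' value, final value, delta (final minus initial), mean, sample standard
#' deviation, variation over time (delta divided by the elapsed interval)
#' and variation-over-time slope (first coefficient of the least-squares
#' line).
#'
#' Initial and final values are means over the first and last second of the
#' phase (single samples are noise-dominated); the variation-over-time
#' denominator is the time between the centres of those two windows, so
#' that on a noiseless linear trend delta, variation and slope are mutually
#' consistent (variation equals slope exactly).
#'
#' @param series A `channel_recording` (raw temperature or the output of
#'   [estimate_derivative()]).
#' @param prefix Name prefix for the returned features (e.g. `"temp"` or
#'   `"dtemp"`); defaults by channel kind.
#' @return Named numeric vector of 7 features:
#'   `<prefix>_{initial,final,delta,mean,sd,variation,variation_slope}`.
#' @examples
#' ramp <- channel_recording(33 - 0.01 * seq(0, 100, by = 0.1), fs = 10, kind = "temp")
#' temperature_features(ramp)[["temp_delta"]]
#' @export
temperature_features <- function(series, prefix = NULL) {
  stopifnot(inherits(series, "channel_recording"))
  v <- series$values
  if (length(v) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (is.null(prefix)) {
    prefix <- if (identical(series$kind, "temp_derivative")) "dtemp" else "temp"
  }
  fs <- series$fs
  t <- (seq_along(v) - 1L) / fs
  n_edge <- max(1L, min(round(fs), floor(length(v) / 2)))
  i_first <- seq_len(n_edge)
  i_last <- seq.int(length(v) - n_edge + 1L, length(v))
  initial <- mean(v[i_first])
  final <- mean(v[i_last])
  delta <- final - initial
  span <- mean(t[i_last]) - mean(t[i_first])
  slope <- sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
  out <- c(initial = initial, final = final, delta = delta,
           mean = mean(v), sd = stats::sd(v),
           variation = delta / span, variation_slope = slope)
  names(out) <- paste(prefix, names(out), sep = "_")
  out
}
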