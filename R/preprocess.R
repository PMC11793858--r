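#' Acquisition filter chain specification
#'
#' Mirrors the acquisition-side conditioning: a mains notch at 50 Hz, a
#' 30 Hz low-pass on every channel, and a 0.1 Hz high-pass on the PPG only.
#' Filters are applied forward-backward (zero phase) so beat and response
#' timings are not shifted; the family is 4th-order Butterworth for the
#' pass filters and a biquad notch of quality factor `notch_q`.
#'
#' @param notch_hz Notch centre frequency in Hz, or `NULL` to skip (e.g. for
#'   simulated data without mains interference, or fs too low for 50 Hz).
#' @param lowpass_hz Low-pass corner in Hz.
#' @param highpass_hz High-pass corner in Hz, or `NULL` to skip (used for
#'   the PPG channel only in the standard chain).
#' @param notch_q Notch quality factor (centre / -3 dB bandwidth).
#' @param order Butterworth order for low/high-pass stages.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_hz = 50, lowpass_hz = 30, highpass_hz = NULL,
                        notch_q = 30, order = 4) {
  if (!is.null(highpass_hz) && !is.null(lowpass_hz) && highpass_hz >= lowpass_hz) {
    stop("`highpass_hz` must be below `lowpass_hz`", call. = FALSE)
  }
  structure(list(notch_hz = notch_hz, lowpass_hz = lowpass_hz,
                 highpass_hz = highpass_hz, notch_q = notch_q, order = order),
            class = "filter_spec")
}

# Biquad notch (RBJ audio-EQ cookbook form): unit gain everywhere except a
# narrow stopband of width f0/Q centred on f0.
notch_coefficients <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Apply the acquisition filter chain to a channel
#'
#' All stages are applied zero-phase (forward-backward, [signal::filtfilt()])
#' so that downstream timing features (beat feet, SCR peaks) are unshifted.
#' Stages whose corner is `NULL` are skipped; any stage at or above the
#' Nyquist frequency is an error.
#'
#' @param rec A `channel_recording`.
#' @param spec A [filter_spec()].
#' @return A filtered `channel_recording` of the same length, rate and kind.
#' @examples
#' tone <- channel_recording(sin(2 * pi * 5 * seq(0, 2, by = 1/500)), 500)
#' filt <- apply_filters(tone, filter_spec(notch_hz = 50))
#' @export
apply_filters <- function(rec, spec) {
  stopifnot(inherits(rec, "channel_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$fs / 2
  for (f in c(spec$notch_hz, spec$lowpass_hz, spec$highpass_hz)) {
    if (f >= nyq) {
      stop(sprintf("filter frequency %g Hz is not below Nyquist (%g Hz)", f, nyq),
           call. = FALSE)
    }
  }
  x <- rec$values
  if (!is.null(spec$notch_hz)) {
    co <- notch_coefficients(spec$notch_hz, rec$fs, spec$notch_q)
    x <- zp_filtfilt(co, x, rec$fs, pad_s = spec$notch_q / spec$notch_hz)
  }
  if (!is.null(spec$lowpass_hz)) {
    bw <- signal::butter(spec$order, spec$lowpass_hz / nyq, type = "low")
    x <- zp_filtfilt(bw, x, rec$fs, pad_s = 1.5 / spec$lowpass_hz)
  }
  if (!is.null(spec$highpass_hz)) {
    bw <- signal::butter(spec$order, spec$highpass_hz / nyq, type = "high")
    x <- zp_filtfilt(bw, x, rec$fs, pad_s = 1.5 / spec$highpass_hz)
  }
  channel_recording(x, rec$fs, rec$kind, rec$t0)
}

#' Cut a recording into protocol phases
#'
#' @param rec A `channel_recording`.
#' @param boundaries List (or data.frame with columns `start`, `end`) of
#'   non-overlapping `[start, end)` spans in seconds, relative to the record
#'   clock.
#' @return List of `channel_recording` segments, each with attribute
#'   `phase` (its index in `boundaries`) and `t0` set to its start time.
#' @export
segment_phases <- function(rec, boundaries) {
  stopifnot(inherits(rec, "channel_recording"))
  if (is.data.frame(boundaries)) {
    boundaries <- lapply(seq_len(nrow(boundaries)),
                         function(i) c(boundaries$start[i], boundaries$end[i]))
  }
  dur <- duration(rec)
  spans <- do.call(rbind, lapply(boundaries, function(b) c(b[1], b[2])))
  if (any(spans[, 2] <= spans[, 1])) stop("phase boundaries must have end > start", call. = FALSE)
  ord <- order(spans[, 1])
  if (any(spans[ord, 1][-1] < spans[ord, 2][-nrow(spans)])) {
    stop("phase boundaries must not overlap", call. = FALSE)
  }
  out <- vector("list", length(boundaries))
  for (i in seq_along(boundaries)) {
    b <- boundaries[[i]]
    rel <- b - rec$t0
    if (rel[1] < 0 || rel[2] > dur + 1e-9) {
      stop(sprintf("phase %d boundary [%g, %g] s lies outside the record (%.3f s)",
                   i, b[1], b[2], dur), call. = FALSE)
    }
    i1 <- floor(rel[1] * rec$fs) + 1L
    i2 <- min(floor(rel[2] * rec$fs), length(rec$values))
    seg <- channel_recording(rec$values[i1:i2], rec$fs, rec$kind,
                             t0 = rec$t0 + (i1 - 1L) / rec$fs)
    attr(seg, "phase") <- i
    out[[i]] <- seg
  }
  out
}

#' Split a segment into fixed-width analysis windows
#'
#' Default windows are 10 s, non-overlapping (`step_s = width_s`); a
#' trailing partial window is discarded rather than padded, so every
#' window statistic is computed on a full `width_s` of signal.
#'
#' @param segment A `channel_recording`.
#' @param width_s Window width in seconds (default 10).
#' @param step_s Hop between window starts in seconds (default `width_s`).
#' @return List of `channel_recording` windows, each with attribute
#'   `window` (index).
#' @examples
#' seg <- channel_recording(rnorm(3000), fs = 10)
#' length(make_windows(seg))  # 30 windows of 10 s
#' @export
make_windows <- function(segment, width_s = 10, step_s = width_s) {
  stopifnot(inherits(segment, "channel_recording"), width_s > 0, step_s > 0)
  dur <- duration(segment)
  if (width_s > dur) {
    stop(sprintf("window width (%g s) exceeds segment duration (%g s)", width_s, dur),
         call. = FALSE)
  }
  wlen <- round(width_s * segment$fs)
  hop <- round(step_s * segment$fs)
  n <- length(segment$values)
  starts <- seq(1L, n - wlen + 1L, by = hop)
  lapply(seq_along(starts), function(i) {
    i1 <- starts[i]
    w <- channel_recording(segment$values[i1:(i1 + wlen - 1L)], segment$fs,
                           segment$kind, t0 = segment$t0 + (i1 - 1L) / segment$fs)
    attr(w, "window") <- i
    w
  })
}
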