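#' Detect beats in a photoplethysmogram
#'
#' Adaptive-threshold peak picking on a band-passed (0.5-8 Hz) copy of the
#' signal with a 0.3 s refractory period, followed by foot location. The
#' foot of each beat is the last pre-peak sample within a noise tolerance
#' of the preceding minimum (i.e. the end of the diastolic baseline, where
#' the upstroke leaves the noise floor): on clean signals this recovers the
#' pulse onset to within one sample, and on noisy signals the crossing is
#' taken on a low-pass smoothed copy with a tolerance tied to the estimated
#' noise level. Amplitudes are peak minus foot value in input units.
#'
#' @param ppg A `channel_recording` of kind `"ppg"`, at least 10 s long,
#'   sampled at >= 50 Hz.
#' @param refractory_s Minimum spacing between accepted peaks (default 0.3 s).
#' @return An object of class `beat_series`: list with `beat_times` (pulse
#'   feet, s), `peak_times` (s), `amplitudes` (peak minus foot value),
#'   `rise_times` (foot to peak, s), `durations` (foot to next foot, s; `NA`
#'   for the final beat) and `ibis` (`diff(beat_times)`, s).
#' @export
detect_beats <- function(ppg, refractory_s = 0.3) {
  stopifnot(inherits(ppg, "channel_recording"))
  if (duration(ppg) < 10) stop("PPG record must be at least 10 s long", call. = FALSE)
  if (ppg$fs < 50) stop("PPG sampling rate must be >= 50 Hz", call. = FALSE)
  fs <- ppg$fs
  x <- ppg$values
  hi <- min(8, 0.8 * fs / 2)
  bp <- signal::butter(2, c(0.5, hi) / (fs / 2), type = "pass")
  z <- zp_filtfilt(bp, x, fs, pad_s = 3)
  amp_scale <- stats::quantile(z, 0.95)
  x_scale <- max(abs(x - stats::median(x)))
  if (!is.finite(amp_scale) || x_scale <= 1e-12 * max(1, abs(stats::median(x))) ||
      amp_scale <= 1e-6 * x_scale) {
    stop("insufficient beats: no pulsatile content detected", call. = FALSE)
  }
  thr <- 0.4 * amp_scale
  n <- length(z)
  is_max <- c(FALSE, z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n], FALSE)
  cand <- which(is_max & z > thr)
  if (length(cand) < 2L) stop("insufficient beats: fewer than 2 peaks found", call. = FALSE)
  # refractory: within `refractory_s` of the last accepted peak keep the taller
  refr <- round(refractory_s * fs)
  keep <- cand[1L]
  for (i in cand[-1L]) {
    last <- keep[length(keep)]
    if (i - last < refr) {
      if (z[i] > z[last]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  if (length(keep) < 2L) stop("insufficient beats: fewer than 2 peaks found", call. = FALSE)
  med_ibi <- stats::median(diff(keep)) / fs
  # noise level from first differences (robust: the baseline dominates the
  # median); decides whether foot location can run on the raw samples
  sigma_hat <- 1.4826 * stats::mad(diff(x), center = 0) / sqrt(2)
  amp_range <- stats::quantile(x, 0.98) - stats::quantile(x, 0.02)
  clean <- sigma_hat < 0.01 * amp_range
  f_sm <- min(10, 0.8 * fs / 2)
  xs <- if (clean) x else {
    zp_filtfilt(signal::butter(4, f_sm / (fs / 2), type = "low"), x, fs,
                pad_s = 1.5 / f_sm, detrend = TRUE)
  }
  sm_resid <- 1.4826 * stats::mad(x - xs)
  half <- round(0.1 * fs)
  back <- max(2L, round(0.6 * med_ibi * fs))
  peaks <- integer(length(keep))
  feet <- integer(length(keep))
  for (k in seq_along(keep)) {
    j <- keep[k]
    w <- max(1L, j - half):min(n, j + half)
    peaks[k] <- w[which.max(xs[w])]
    if (peaks[k] <= 1L) next
    w2 <- max(1L, peaks[k] - back):(peaks[k] - 1L)
    mn <- min(xs[w2])
    amp_k <- xs[peaks[k]] - mn
    tol <- if (clean) 1e-6 * amp_k else 3 * sm_resid + 0.002 * amp_k
    feet[k] <- max(w2[xs[w2] <= mn + tol])   # last sample still at the baseline
  }
  ok0 <- feet > 0L
  peaks <- peaks[ok0]; feet <- feet[ok0]
  ok <- !duplicated(feet)
  peaks <- peaks[ok]; feet <- feet[ok]
  if (length(feet) < 2L) stop("insufficient beats: fewer than 2 beats resolved", call. = FALSE)
  beat_times <- ppg$t0 + (feet - 1L) / fs
  peak_times <- ppg$t0 + (peaks - 1L) / fs
  ibis <- diff(beat_times)
  structure(list(beat_times = beat_times,
                 peak_times = peak_times,
                 amplitudes = xs[peaks] - xs[feet],
                 rise_times = peak_times - beat_times,
                 durations = c(ibis, NA_real_),
                 ibis = ibis),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series: %d beats, mean IBI %.3f s>\n",
              length(x$beat_times), mean(x$ibis)))
  invisible(x)
}

#' Construct a beat series from known beat times
#'
#' Used to bypass detection when ground-truth beats are available (e.g. from
#' the simulator).
#'
#' @param beat_times Strictly increasing pulse-foot times in seconds.
#' @param amplitudes,rise_times Optional per-beat morphology (default `NA`).
#' @return A `beat_series`.
#' @export
beat_series <- function(beat_times, amplitudes = NULL, rise_times = NULL) {
  stopifnot(length(beat_times) >= 2L, all(diff(beat_times) > 0))
  n <- length(beat_times)
  ibis <- diff(beat_times)
  structure(list(beat_times = beat_times,
                 peak_times = if (is.null(rise_times)) rep(NA_real_, n) else beat_times + rise_times,
                 amplitudes = if (is.null(amplitudes)) rep(NA_real_, n) else amplitudes,
                 rise_times = if (is.null(rise_times)) rep(NA_real_, n) else rise_times,
                 durations = c(ibis, NA_real_),
                 ibis = ibis),
            class = "beat_series")
}

#' Pulse-shape features over 10-s windows
#'
#' For each analysis window, the mean, sample standard deviation and median
#' of the per-beat amplitude, duration and rise time are computed over the
#' beats whose foot falls in the window; the window-level statistics are
#' then averaged across windows to give one value per phase. Windows holding
#' fewer than two beats are skipped with a warning.
#'
#' @param beats A `beat_series`.
#' @param windows List of windows from [make_windows()], or a two-column
#'   matrix of `[start, end)` spans in seconds.
#' @return Named numeric vector of 9 features:
#'   `ppg_{amplitude,duration,rise_time}_{mean,sd,median}`.
#' @export
ppg_shape_features <- function(beats, windows) {
  stopifnot(inherits(beats, "beat_series"))
  spans <- if (is.matrix(windows)) {
    windows
  } else {
    do.call(rbind, lapply(windows, function(w) c(w$t0, w$t0 + duration(w))))
  }
  per_window <- list()
  for (i in seq_len(nrow(spans))) {
    in_w <- beats$beat_times >= spans[i, 1] & beats$beat_times < spans[i, 2]
    if (sum(in_w) < 2L) {
      warning(sprintf("window %d has fewer than 2 beats; skipped", i), call. = FALSE)
      next
    }
    stat3 <- function(v) {
      v <- v[!is.na(v)]
      c(mean = mean(v), sd = stats::sd(v), median = stats::median(v))
    }
    per_window[[length(per_window) + 1L]] <- c(
      amplitude = stat3(beats$amplitudes[in_w]),
      duration = stat3(beats$durations[in_w]),
      rise_time = stat3(beats$rise_times[in_w]))
  }
  if (!length(per_window)) stop("no window contained at least 2 beats", call. = FALSE)
  agg <- colMeans(do.call(rbind, per_window))
  names(agg) <- paste0("ppg_", sub("\\.", "_", names(agg)))
  agg
}

#' Beats-per-minute trend on a uniform grid
#'
#' The instantaneous rate 60/IBI is assigned at beat times (each beat after
#' the first carries the rate of the interval it closes; the first beat
#' repeats the first interval's rate) and linearly interpolated onto a
#' uniform grid spanning exactly `[first beat, last beat]` — no
#' extrapolation.
#'
#' @param beats A `beat_series` with at least 3 beats.
#' @param grid_hz Grid rate in Hz (default 4).
#' @return An object of class `bpm_trend`: list with `times` (s), `bpm`
#'   (beats/min) and `fs` (= `grid_hz`).
#' @export
bpm_trend <- function(beats, grid_hz = 4) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$beat_times) < 3L) stop("need at least 3 beats for a BPM trend", call. = FALSE)
  bt <- beats$beat_times
  inst <- 60 / c(beats$ibis[1L], beats$ibis)
  grid <- seq(bt[1L], bt[length(bt)], by = 1 / grid_hz)
  bpm <- stats::approx(bt, inst, xout = grid)$y
  structure(list(times = grid, bpm = bpm, fs = grid_hz), class = "bpm_trend")
}

#' @export
print.bpm_trend <- function(x, ...) {
  cat(sprintf("<bpm_trend: %.1f s @ %g Hz, mean %.1f BPM>\n",
              diff(range(x$times)), x$fs, mean(x$bpm)))
  invisible(x)
}

#' Heart-rate-variability spectral bands of the BPM trend
#'
#' Low frequency (PLF) spans `[0.04, 0.15)` Hz and high frequency (PHF)
#' spans `[0.15, 0.4]` Hz; the 0.15 Hz boundary belongs to PHF so the two
#' bands partition the 0.04-0.4 Hz range without double counting.
#'
#' @param plf,phf Band edges in Hz.
#' @return An object of class `spectral_bands`.
#' @export
spectral_bands <- function(plf = c(0.04, 0.15), phf = c(0.15, 0.4)) {
  stopifnot(length(plf) == 2L, length(phf) == 2L, plf[2] == phf[1])
  structure(list(plf = plf, phf = phf), class = "spectral_bands")
}

# One-sided short-time PSD with a Hann window. Columns are time frames.
# Scaling: P(f) = |X(f)|^2 / (fs * sum(w^2)), doubled off DC/Nyquist, so
# sum(P) * df equals the Hann-weighted variance sum(w^2 x^2)/sum(w^2) of
# each frame (discrete Parseval).
stft_psd <- function(x, fs, window_s = 60, overlap = 0.5) {
  L <- round(window_s * fs)
  hop <- max(1L, round(L * (1 - overlap)))
  if (length(x) < L + hop) stop("signal too short for a short-time spectrum", call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  nb <- floor(L / 2) + 1L
  P <- matrix(0, nb, length(starts))
  W <- sum(w^2)
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + L - 1L)] * w
    X <- stats::fft(seg)[seq_len(nb)]
    p <- Mod(X)^2 / (fs * W)
    dbl <- rep(2, nb); dbl[1L] <- 1
    if (L %% 2 == 0) dbl[nb] <- 1
    P[, j] <- p * dbl
  }
  list(freq = (seq_len(nb) - 1L) * fs / L,
       time = (starts - 1L + L / 2) / fs,
       psd = P, df = fs / L)
}

band_power <- function(sp, lo, hi, closed_hi = FALSE) {
  sel <- if (closed_hi) sp$freq >= lo & sp$freq <= hi else sp$freq >= lo & sp$freq < hi
  colSums(sp$psd[sel, , drop = FALSE]) * sp$df
}

#' Heart-rate and heart-rate-variability features
#'
#' Time-domain features come from the BPM trend (mean, sample SD, median)
#' and the inter-beat intervals (pNN50, the percentage of successive IBI
#' differences exceeding 50 ms in absolute value, and RMSSD in ms).
#' Frequency-domain features integrate a short-time periodogram (Hann
#' window, default 60 s with 50\% overlap) of the mean-removed trend over
#' the PLF and PHF bands, yielding per-frame band powers whose mean and SD
#' over time are reported, together with the mean, SD and median of the
#' per-frame PLF/PHF ratio.
#'
#' @param beats A `beat_series` (source of the IBIs).
#' @param trend A `bpm_trend`; computed from `beats` when `NULL`.
#' @param bands A [spectral_bands()].
#' @param window_s,overlap Short-time periodogram frame length (s) and
#'   fractional overlap.
#' @return Named numeric vector of 12 features: `bpm_{mean,sd,median}`,
#'   `pnn50`, `hrv_rmssd_ms`, `plf_{mean,sd}`, `phf_{mean,sd}`,
#'   `lf_hf_ratio_{mean,sd,median}`. Spectral entries are `NA` when the
#'   trend is shorter than `window_s`.
#' @examples
#' b <- beat_series(cumsum(c(0, rep(c(0.8, 0.86, 0.82, 0.9, 0.905), 20))))
#' hr_hrv_features(b)[["pnn50"]]
#' @export
hr_hrv_features <- function(beats, trend = NULL, bands = spectral_bands(),
                            window_s = 60, overlap = 0.5) {
  stopifnot(inherits(beats, "beat_series"), inherits(bands, "spectral_bands"))
  if (is.null(trend)) trend <- bpm_trend(beats)
  stopifnot(inherits(trend, "bpm_trend"))
  d_ms <- abs(diff(beats$ibis)) * 1000
  out <- c(bpm_mean = mean(trend$bpm),
           bpm_sd = stats::sd(trend$bpm),
           bpm_median = stats::median(trend$bpm),
           pnn50 = if (length(d_ms)) 100 * mean(d_ms > 50) else NA_real_,
           hrv_rmssd_ms = if (length(d_ms)) sqrt(mean(d_ms^2)) else NA_real_)
  span <- diff(range(trend$times))
  spec <- c(plf_mean = NA_real_, plf_sd = NA_real_, phf_mean = NA_real_,
            phf_sd = NA_real_, lf_hf_ratio_mean = NA_real_,
            lf_hf_ratio_sd = NA_real_, lf_hf_ratio_median = NA_real_)
  if (span >= window_s + (1 - overlap) * window_s) {
    sp <- stft_psd(trend$bpm - mean(trend$bpm), trend$fs, window_s, overlap)
    plf <- band_power(sp, bands$plf[1], bands$plf[2], closed_hi = FALSE)
    phf <- band_power(sp, bands$phf[1], bands$phf[2], closed_hi = TRUE)
    ratio <- plf / pmax(phf, .Machine$double.xmin)
    spec <- c(plf_mean = mean(plf), plf_sd = stats::sd(plf),
              phf_mean = mean(phf), phf_sd = stats::sd(phf),
              lf_hf_ratio_mean = mean(ratio), lf_hf_ratio_sd = stats::sd(ratio),
              lf_hf_ratio_median = stats::median(ratio))
  }
  c(out, spec)
}

#' Short-time spectrogram of the BPM trend
#'
#' The time-frequency power map used to visualize shifts between the low-
#' and high-frequency heart-rate-variability bands during a protocol.
#'
#' @inheritParams hr_hrv_features
#' @param trend A `bpm_trend` spanning at least `window_s * (2 - overlap)` s.
#' @return An object of class `bpm_spectrogram`: list with `freq` (Hz),
#'   `time` (s, frame centres), `psd` (frequency x time, units BPM^2/Hz)
#'   and `df` (bin width, Hz).
#' @export
bpm_spectrogram <- function(trend, window_s = 60, overlap = 0.5) {
  stopifnot(inherits(trend, "bpm_trend"))
  sp <- stft_psd(trend$bpm - mean(trend$bpm), trend$fs, window_s, overlap)
  sp$time <- sp$time + trend$times[1L]
  structure(sp, class = "bpm_spectrogram")
}

#' @export
print.bpm_spectrogram <- function(x, ...) {
  cat(sprintf("<bpm_spectrogram: %d freq bins x %d frames, df = %.4f Hz>\n",
              nrow(x$psd), ncol(x$psd), x$df))
  invisible(x)
}
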