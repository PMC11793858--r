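#' Simulate an inter-beat-interval series with planted spectral content
#'
#' Generates successive inter-beat intervals (IBIs) whose slow modulation
#' carries known power in the two heart-rate-variability bands: a 0.1 Hz
#' sinusoid (centre of the 0.04-0.15 Hz low-frequency band) and a 0.25 Hz
#' sinusoid (centre of the 0.15-0.4 Hz high-frequency band), plus white
#' jitter:
#' \deqn{IBI(t) = \mu + a_{LF} \sin(2\pi\, 0.1 t) + a_{HF} \sin(2\pi\, 0.25 t) + \epsilon.}
#' The class label scales \eqn{\mu}, \eqn{a_{LF}} and \eqn{a_{HF}} through
#' the [effect_spec()] multipliers, so downstream spectral features have a
#' known ground truth.
#'
#' @param effect An [effect_spec()].
#' @param cls Class label in 0:4.
#' @param duration_s Target duration in seconds; intervals are emitted until
#'   their cumulative sum reaches it.
#' @param seed Integer seed; identical arguments give identical output.
#' @return Numeric vector of IBIs in seconds, all positive, whose cumulative
#'   sum is >= `duration_s`.
#' @details Parameters that could produce an IBI at or below 0.3 s
#'   (`a_LF + a_HF + 4 sd >= mu - 0.3`) are rejected: 0.3 s is the refractory
#'   floor assumed by the beat detector. Draws beyond the 4-sd guard band
#'   are clamped at 0.3 s.
#' @export
simulate_ibi_series <- function(effect, cls, duration_s, seed = 1L) {
  stopifnot(inherits(effect, "effect_spec"), duration_s > 0)
  cls <- check_class_label(cls)
  mu <- effect$ibi_mean_s * effect$ibi_mean_mult[cls + 1L]
  a_lf <- effect$ibi_lf_amp_s * effect$ibi_lf_mult[cls + 1L]
  a_hf <- effect$ibi_hf_amp_s * effect$ibi_hf_mult[cls + 1L]
  sd <- effect$ibi_noise_sd_s
  if (a_lf + a_hf + 4 * sd >= mu - 0.3) {
    stop("IBI parameters can produce intervals <= 0.3 s: need a_LF + a_HF + 4*sd < mu - 0.3",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    n_max <- ceiling(duration_s / (mu - a_lf - a_hf - 4 * sd)) + 8L
    ibis <- numeric(n_max)
    t <- 0
    i <- 0L
    while (t < duration_s) {
      i <- i + 1L
      ibi <- mu + a_lf * sin(2 * pi * 0.1 * t) + a_hf * sin(2 * pi * 0.25 * t) +
        stats::rnorm(1L, 0, sd)
      ibi <- max(ibi, 0.3)
      ibis[i] <- ibi
      t <- t + ibi
    }
    ibis[seq_len(i)]
  })
}

# Unit-amplitude pulse template sampled at fs: half-cosine rise over rise_s,
# then exponential decay over (width_s - rise_s) renormalized to end at 0.
pulse_template <- function(rise_s, width_s, fs) {
  stopifnot(rise_s > 0, width_s > rise_s)
  t <- seq(0, width_s, by = 1 / fs)
  tau <- (width_s - rise_s) / 5
  y <- ifelse(t <= rise_s,
              0.5 * (1 - cos(pi * t / rise_s)),
              (exp(-(t - rise_s) / tau) - exp(-5)) / (1 - exp(-5)))
  y
}

#' Synthesize a photoplethysmogram from an IBI series
#'
#' Places one pulse template per beat at the cumulative IBI onsets. The
#' template has a half-cosine rise (fast upstroke) followed by an
#' exponential decay; rise time and amplitude are class-modulated through
#' the [effect_spec()]. Additive white noise models sensor noise.
#'
#' @inheritParams simulate_ibi_series
#' @param ibis Numeric vector of inter-beat intervals in seconds.
#' @param fs Sampling rate in Hz (>= 50).
#' @param noise_sd Override for the PPG noise SD; default taken from `effect`.
#' @return A list with `rec` (a `channel_recording` of kind `"ppg"`) and
#'   `beat_times` (the pulse onset, i.e. foot, times in seconds).
#' @export
synthesize_ppg <- function(ibis, effect, cls, fs, seed = 1L, noise_sd = NULL) {
  stopifnot(inherits(effect, "effect_spec"))
  cls <- check_class_label(cls)
  if (length(ibis) < 1L) stop("`ibis` must contain at least one interval", call. = FALSE)
  if (any(ibis <= 0)) stop("all IBIs must be positive", call. = FALSE)
  if (fs < 50) stop("`fs` must be >= 50 Hz for beat morphology", call. = FALSE)
  amp <- effect$pulse_amp * effect$pulse_amp_mult[cls + 1L]
  rise <- effect$pulse_rise_s * effect$pulse_rise_mult[cls + 1L]
  width <- effect$pulse_width_s
  if (width >= min(ibis)) {
    stop(sprintf("pulse duration (%.3f s) must be shorter than the smallest IBI (%.3f s)",
                 width, min(ibis)), call. = FALSE)
  }
  if (is.null(noise_sd)) noise_sd <- effect$ppg_noise_sd
  onsets <- c(0, cumsum(ibis))       # feet; last onset starts the final pulse
  dur <- onsets[length(onsets)] + width + 1 / fs
  n <- ceiling(dur * fs)
  tmpl <- amp * pulse_template(rise, width, fs)
  x <- numeric(n)
  idx0 <- round(onsets * fs) + 1L
  for (i0 in idx0) {
    j <- i0:(i0 + length(tmpl) - 1L)
    keep <- j <= n
    x[j[keep]] <- x[j[keep]] + tmpl[keep]
  }
  x <- x + withr::with_seed(seed, stats::rnorm(n, 0, noise_sd))
  list(rec = channel_recording(x, fs, "ppg"), beat_times = onsets)
}

#' Bateman (biexponential) skin-conductance-response kernel
#'
#' \eqn{k(t) = e^{-t/\tau_2} - e^{-t/\tau_1}} for \eqn{t \ge 0},
#' with \eqn{\tau_1 < \tau_2}; its maximum is at
#' \eqn{t^* = \tau_1\tau_2/(\tau_2-\tau_1)\,\log(\tau_2/\tau_1)}.
#'
#' @param t Time points in seconds.
#' @param tau1,tau2 Rise and decay constants in seconds, `tau1 < tau2`.
#' @return Kernel values (0 for `t < 0`).
#' @export
bateman_kernel <- function(t, tau1 = 0.7, tau2 = 3.0) {
  stopifnot(tau1 > 0, tau1 < tau2)
  ifelse(t < 0, 0, exp(-t / tau2) - exp(-t / tau1))
}

#' Synthesize an electrodermal activity channel with ground truth
#'
#' EDA is modelled as a slow tonic component (level plus linear drift) plus
#' a sparse train of skin-conductance responses — Poisson-timed events
#' convolved with the [bateman_kernel()] — plus white noise. Event rate,
#' tonic level and tonic slope are class-modulated.
#'
#' @inheritParams simulate_ibi_series
#' @param fs Sampling rate in Hz.
#' @param event_times,event_amps Optional explicit event times (s) and
#'   driver amplitudes (microsiemens); default draws Poisson-timed events.
#' @return A list with `rec` (a `channel_recording` of kind `"eda"`) and
#'   `truth`, a list holding `scr_event_times`, `scr_event_amplitudes`,
#'   `tonic_curve` (microsiemens at each sample) and the realized `rate_per_min`.
#' @export
synthesize_eda <- function(effect, cls, duration_s, fs, seed = 1L,
                           event_times = NULL, event_amps = NULL) {
  stopifnot(inherits(effect, "effect_spec"), duration_s > 0, fs > 0)
  cls <- check_class_label(cls)
  level <- effect$scl_level_uS + effect$scl_level_offset_uS[cls + 1L]
  slope <- effect$scl_slope_uS_s + effect$scl_slope_offset_uS_s[cls + 1L]
  rate <- effect$scr_rate_per_min * effect$scr_rate_mult[cls + 1L]
  n <- round(duration_s * fs)
  t <- (0:(n - 1L)) / fs
  withr::with_seed(seed, {
    if (is.null(event_times)) {
      n_ev <- stats::rpois(1L, rate * duration_s / 60)
      event_times <- sort(stats::runif(n_ev, 0, duration_s))
      event_amps <- effect$scr_amp_uS *
        stats::rlnorm(n_ev, meanlog = 0, sdlog = 0.3)
    } else {
      stopifnot(length(event_times) == length(event_amps), all(event_amps >= 0))
      ord <- order(event_times)
      event_times <- event_times[ord]
      event_amps <- event_amps[ord]
    }
    noise <- stats::rnorm(n, 0, effect$eda_noise_sd_uS)
  })
  tonic <- level + slope * t
  phasic <- numeric(n)
  for (i in seq_along(event_times)) {
    phasic <- phasic + event_amps[i] *
      bateman_kernel(t - event_times[i], effect$scr_tau1_s, effect$scr_tau2_s)
  }
  truth <- list(scr_event_times = event_times,
                scr_event_amplitudes = event_amps,
                tonic_curve = tonic,
                rate_per_min = rate)
  list(rec = channel_recording(tonic + phasic + noise, fs, "eda"), truth = truth)
}

#' Synthesize a skin-temperature channel
#'
#' Linear drift from a baseline temperature, with a class-dependent slope,
#' plus autocorrelated (AR(1)) noise whose marginal standard deviation is
#' `temp_noise_sd_C` and whose correlation time is `temp_noise_tau_s`.
#'
#' @inheritParams synthesize_eda
#' @return A list with `rec` (a `channel_recording` of kind `"temp"`) and
#'   `truth` holding the noiseless `trend` and its `slope_C_s`.
#' @export
synthesize_temperature <- function(effect, cls, duration_s, fs, seed = 1L) {
  stopifnot(inherits(effect, "effect_spec"), duration_s > 0, fs > 0)
  cls <- check_class_label(cls)
  slope <- effect$temp_slope_C_s + effect$temp_slope_offset_C_s[cls + 1L]
  n <- round(duration_s * fs)
  t <- (0:(n - 1L)) / fs
  trend <- effect$temp_initial_C + slope * t
  sd <- effect$temp_noise_sd_C
  noise <- if (sd > 0) {
    phi <- exp(-1 / (effect$temp_noise_tau_s * fs))
    innov_sd <- sd * sqrt(1 - phi^2)   # marginal sd stays at `sd`
    withr::with_seed(seed,
      as.numeric(stats::arima.sim(list(ar = phi), n, sd = innov_sd)))
  } else {
    numeric(n)
  }
  list(rec = channel_recording(trend + noise, fs, "temp"),
       truth = list(trend = trend, slope_C_s = slope))
}
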