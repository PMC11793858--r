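#' Class-dependent effect specification for the cohort simulator
#'
#' Encodes how each latent cognitive-state class (0 = rest baseline,
#' 1-4 = increasing perceived stress / mental workload) modulates the
#' simulated physiology. Multipliers are relative to the class-0 baseline
#' (so entry 1 must equal 1), offsets are additive (entry 1 must equal 0).
#'
#' No published effect sizes link the class labels to physiological
#' quantities, so the defaults are validation settings, not physiological
#' claims: higher classes shorten the mean inter-beat interval (higher heart
#' rate), shift inter-beat variability from the high-frequency to the
#' low-frequency band, damp the pulse, raise the skin-conductance level and
#' response rate, and cool the finger faster.
#'
#' @param ibi_mean_s Baseline mean inter-beat interval, seconds.
#' @param ibi_mean_mult Length-5 multiplier on the mean IBI per class.
#' @param ibi_lf_amp_s,ibi_hf_amp_s Baseline amplitudes (s) of the 0.1 Hz
#'   and 0.25 Hz IBI modulations.
#' @param ibi_lf_mult,ibi_hf_mult Length-5 multipliers on those amplitudes.
#' @param ibi_noise_sd_s White IBI jitter SD, seconds.
#' @param pulse_amp Baseline pulse amplitude (arbitrary units).
#' @param pulse_amp_mult Length-5 multiplier on pulse amplitude.
#' @param pulse_rise_s Baseline pulse foot-to-peak rise time, seconds.
#' @param pulse_rise_mult Length-5 multiplier on rise time.
#' @param pulse_width_s Pulse duration (foot to return-to-baseline), seconds.
#' @param ppg_noise_sd Additive PPG noise SD, signal units.
#' @param scl_level_uS Baseline tonic skin conductance, microsiemens.
#' @param scl_level_offset_uS Length-5 additive offset on the tonic level.
#' @param scl_slope_uS_s Baseline tonic slope, microsiemens per second.
#' @param scl_slope_offset_uS_s Length-5 additive offset on the tonic slope.
#' @param scr_rate_per_min Baseline skin-conductance-response event rate,
#'   events per minute.
#' @param scr_rate_mult Length-5 multiplier on the event rate.
#' @param scr_amp_uS Mean planted SCR driver amplitude, microsiemens.
#' @param eda_noise_sd_uS Additive EDA noise SD, microsiemens.
#' @param scr_tau1_s,scr_tau2_s Bateman kernel time constants (rise, decay).
#' @param temp_initial_C Baseline skin temperature at phase start, Celsius.
#' @param temp_slope_C_s Baseline drift slope, Celsius per second.
#' @param temp_slope_offset_C_s Length-5 additive offset on the drift slope.
#' @param temp_noise_sd_C Marginal SD of the autocorrelated temperature
#'   noise, Celsius.
#' @param temp_noise_tau_s Autocorrelation time constant of the temperature
#'   noise, seconds (AR(1) with phi = exp(-1/(tau * fs))).
#'
#' @return An object of class `effect_spec` (a validated named list).
#' @export
effect_spec <- function(ibi_mean_s = 0.85,
                        ibi_mean_mult = c(1, 0.97, 0.94, 0.90, 0.86),
                        ibi_lf_amp_s = 0.020,
                        ibi_lf_mult = c(1, 1.3, 1.6, 2.0, 2.4),
                        ibi_hf_amp_s = 0.030,
                        ibi_hf_mult = c(1, 0.85, 0.70, 0.55, 0.40),
                        ibi_noise_sd_s = 0.01,
                        pulse_amp = 1.0,
                        pulse_amp_mult = c(1, 0.95, 0.90, 0.85, 0.80),
                        pulse_rise_s = 0.15,
                        pulse_rise_mult = c(1, 0.97, 0.94, 0.91, 0.88),
                        pulse_width_s = 0.45,
                        ppg_noise_sd = 0.05,
                        scl_level_uS = 2.0,
                        scl_level_offset_uS = c(0, 0.5, 1.0, 1.5, 2.0),
                        scl_slope_uS_s = 0.0,
                        scl_slope_offset_uS_s = c(0, 1, 2, 3, 4) * 5e-4,
                        scr_rate_per_min = 2,
                        scr_rate_mult = c(1, 2, 3, 4, 5),
                        scr_amp_uS = 0.5,
                        eda_noise_sd_uS = 0.01,
                        scr_tau1_s = 0.7,
                        scr_tau2_s = 3.0,
                        temp_initial_C = 33.0,
                        temp_slope_C_s = 0.0,
                        temp_slope_offset_C_s = -c(0, 1, 2, 3, 4) * 2e-3,
                        temp_noise_sd_C = 0.02,
                        temp_noise_tau_s = 1.0) {
  spec <- as.list(environment())
  mults <- c("ibi_mean_mult", "ibi_lf_mult", "ibi_hf_mult", "pulse_amp_mult",
             "pulse_rise_mult", "scr_rate_mult")
  offs <- c("scl_level_offset_uS", "scl_slope_offset_uS_s", "temp_slope_offset_C_s")
  for (nm in c(mults, offs)) {
    v <- spec[[nm]]
    if (length(v) != 5L) stop(sprintf("`%s` must have length 5 (classes 0-4)", nm), call. = FALSE)
  }
  for (nm in mults) {
    if (spec[[nm]][1L] != 1) stop(sprintf("`%s`[1] is the class-0 baseline and must be 1", nm), call. = FALSE)
    if (any(spec[[nm]] < 0)) stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
  }
  for (nm in offs) {
    if (spec[[nm]][1L] != 0) stop(sprintf("`%s`[1] is the class-0 baseline and must be 0", nm), call. = FALSE)
  }
  if (spec$scr_tau1_s >= spec$scr_tau2_s) stop("`scr_tau1_s` must be < `scr_tau2_s`", call. = FALSE)
  if (spec$scr_rate_per_min < 0) stop("`scr_rate_per_min` must be >= 0", call. = FALSE)
  with(spec, stopifnot(ibi_mean_s > 0, pulse_width_s > pulse_rise_s,
                       ppg_noise_sd >= 0, eda_noise_sd_uS >= 0, temp_noise_sd_C >= 0))
  structure(spec, class = "effect_spec")
}

check_class_label <- function(cls) {
  if (!is.numeric(cls) || length(cls) != 1L || !(cls %in% 0:4)) {
    stop("`cls` must be a single class label in 0:4", call. = FALSE)
  }
  as.integer(cls)
}

#' Cohort study configuration
#'
#' Describes the simulated study design: the number of participants, the
#' cognitive tests, the phase structure (one rest phase plus three task
#' sub-phases per test), the acquisition sampling rate, and the distribution
#' of self-assessed class labels over the task phases.
#'
#' The per-class label distribution over classes 1-4 is configurable because
#' the reference allocation is only reported graphically; the default is a
#' skewed vector favouring the middle classes.
#'
#' @param n_participants Number of subjects (default 28).
#' @param tests Character vector of test names.
#' @param n_phases Phases per test, the first being rest (default 4).
#' @param phase_duration_s Seconds per phase (default 300; must be >= 60 so
#'   the low-frequency BPM band is resolvable).
#' @param fs Sampling rate in Hz (acquisition default 1200; lower rates are
#'   fine for simulation studies since all simulated content is < 10 Hz).
#' @param label_distribution Probability vector over classes 1-4 used to
#'   label task phases, or a list of such vectors named by test.
#' @param seed Integer RNG seed for the whole cohort.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 28,
                          tests = c("Stroop", "VisualNBack", "AuditoryNBack", "DualNBack"),
                          n_phases = 4,
                          phase_duration_s = 300,
                          fs = 1200,
                          label_distribution = c(0.15, 0.35, 0.35, 0.15),
                          seed = 1L) {
  stopifnot(n_participants >= 2, n_phases >= 2, length(tests) >= 1)
  if (phase_duration_s < 60) {
    stop("`phase_duration_s` must be >= 60 s to resolve the LF band", call. = FALSE)
  }
  if (!is.list(label_distribution)) {
    label_distribution <- stats::setNames(
      rep(list(label_distribution), length(tests)), tests)
  }
  if (!all(tests %in% names(label_distribution))) {
    stop("`label_distribution` list must be named by test", call. = FALSE)
  }
  for (tn in tests) {
    p <- label_distribution[[tn]]
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("each label distribution must be 4 non-negative probabilities summing to 1",
           call. = FALSE)
    }
  }
  structure(list(n_participants = as.integer(n_participants), tests = tests,
                 n_phases = as.integer(n_phases),
                 phase_duration_s = phase_duration_s, fs = fs,
                 label_distribution = label_distribution,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config: %d subjects x %d tests x %d phases, %g s @ %g Hz>\n",
              x$n_participants, length(x$tests), x$n_phases,
              x$phase_duration_s, x$fs))
  invisible(x)
}
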