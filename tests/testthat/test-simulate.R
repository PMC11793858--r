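eff <- effect_spec()

test_that("noiseless constant IBI series is exactly the configured mean", {
  e0 <- effect_spec(ibi_lf_amp_s = 0, ibi_hf_amp_s = 0, ibi_noise_sd_s = 0,
                    ibi_mean_s = 0.8)
  ibis <- simulate_ibi_series(e0, 0, 30, seed = 1)
  expect_true(all(ibis == 0.8))
  expect_gte(sum(ibis), 30)
})

test_that("IBI simulation is seed-deterministic and always positive", {
  a <- simulate_ibi_series(eff, 2, 120, seed = 11)
  b <- simulate_ibi_series(eff, 2, 120, seed = 11)
  d <- simulate_ibi_series(eff, 2, 120, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, d))
  expect_true(all(a > 0))
  expect_gte(sum(a), 120)
})

test_that("IBI parameters that can go non-positive are rejected", {
  bad <- effect_spec(ibi_mean_s = 0.5, ibi_lf_amp_s = 0.1, ibi_hf_amp_s = 0.1,
                     ibi_noise_sd_s = 0.05)
  expect_error(simulate_ibi_series(bad, 0, 30), "0.3 s")
})

test_that("planted 0.25 Hz IBI modulation lands its power in the HF band", {
  e_hf <- effect_spec(ibi_mean_s = 0.8, ibi_lf_amp_s = 0, ibi_hf_amp_s = 0.05,
                      ibi_noise_sd_s = 0)
  ibis <- simulate_ibi_series(e_hf, 0, 300, seed = 5)
  trend <- bpm_trend(beat_series(cumsum(c(0, ibis))))
  tot <- oracle_band_power(trend$bpm, trend$fs, 0.04, 0.4, closed_hi = TRUE)
  hf <- oracle_band_power(trend$bpm, trend$fs, 0.15, 0.4, closed_hi = TRUE)
  expect_gt(hf / tot, 0.9)
})

test_that("planted 0.1 Hz IBI modulation lands its power in the LF band", {
  e_lf <- effect_spec(ibi_mean_s = 0.8, ibi_lf_amp_s = 0.05, ibi_hf_amp_s = 0,
                      ibi_noise_sd_s = 0)
  ibis <- simulate_ibi_series(e_lf, 0, 300, seed = 5)
  trend <- bpm_trend(beat_series(cumsum(c(0, ibis))))
  tot <- oracle_band_power(trend$bpm, trend$fs, 0.04, 0.4, closed_hi = TRUE)
  lf <- oracle_band_power(trend$bpm, trend$fs, 0.04, 0.15)
  expect_gt(lf / tot, 0.9)
})

test_that("noiseless PPG pulses reach exactly the configured amplitude", {
  e0 <- effect_spec(ibi_lf_amp_s = 0, ibi_hf_amp_s = 0, ibi_noise_sd_s = 0,
                    ppg_noise_sd = 0)
  ibis <- rep(0.8, 20)
  p <- synthesize_ppg(ibis, e0, 0, fs = 100, noise_sd = 0)
  x <- p$rec$values
  n <- length(x)
  locmax <- which(c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE))
  expect_equal(unname(x[locmax]), rep(1.0, length(p$beat_times)), tolerance = 1e-3)
  expect_equal(p$beat_times, cumsum(c(0, ibis)))
})

test_that("PPG synthesis rejects degenerate inputs", {
  expect_error(synthesize_ppg(numeric(0), eff, 0, fs = 100), "at least one")
  expect_error(synthesize_ppg(rep(0.3, 5), eff, 0, fs = 100), "smallest IBI")
  expect_error(synthesize_ppg(rep(0.8, 5), eff, 0, fs = 20), ">= 50")
})

test_that("PPG rise time on the generated waveform matches the template", {
  ibis <- rep(0.85, 30)
  p <- synthesize_ppg(ibis, eff, 0, fs = 200, noise_sd = 0)
  b <- detect_beats(p$rec)
  expect_true(all(abs(b$rise_times - 0.15) <= 1 / 200 + 1e-9))
})

test_that("null-phasic EDA is the tonic curve; pure ramp recovers its slope", {
  e0 <- effect_spec(scr_rate_per_min = 0, eda_noise_sd_uS = 0)
  flat <- synthesize_eda(e0, 0, 60, fs = 20, seed = 1)
  expect_equal(flat$rec$values, rep(2.0, 1200))
  expect_length(flat$truth$scr_event_times, 0)
  er <- effect_spec(scr_rate_per_min = 0, eda_noise_sd_uS = 0,
                    scl_slope_uS_s = 0.01)
  ramp <- synthesize_eda(er, 0, 100, fs = 20, seed = 1)
  t <- sample_times(ramp$rec)
  expect_equal(unname(coef(lm(ramp$rec$values ~ t))[2]), 0.01, tolerance = 1e-10)
})

test_that("a single planted SCR peaks at amplitude times the kernel maximum", {
  e0 <- effect_spec(eda_noise_sd_uS = 0)
  a <- 0.6
  out <- synthesize_eda(e0, 0, 60, fs = 20, seed = 1,
                        event_times = 20, event_amps = a)
  tau1 <- e0$scr_tau1_s; tau2 <- e0$scr_tau2_s
  t_star <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  k_max <- bateman_kernel(t_star, tau1, tau2)
  expect_equal(max(out$rec$values) - 2.0, a * k_max, tolerance = 1e-3)
})

test_that("planted SCR event counts follow the Poisson mean over replicates", {
  e3 <- effect_spec(scr_rate_per_min = 3, scr_rate_mult = rep(1, 5))
  lam <- 3 * 120 / 60   # expected events per 120 s phase
  counts <- vapply(1:100, function(s) {
    length(synthesize_eda(e3, 1, 120, fs = 4, seed = s)$truth$scr_event_times)
  }, numeric(1))
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / 100))
})

test_that("temperature drift is exact without noise and unbiased with noise", {
  e0 <- effect_spec(temp_noise_sd_C = 0)
  flat <- synthesize_temperature(e0, 0, 50, fs = 10, seed = 1)
  expect_equal(flat$rec$values, rep(33, 500))
  es <- effect_spec(temp_noise_sd_C = 0, temp_slope_C_s = -0.01,
                    temp_slope_offset_C_s = rep(0, 5))
  drift <- synthesize_temperature(es, 0, 100, fs = 10, seed = 1)
  v <- drift$rec$values
  expect_equal(v[1], 33)
  expect_equal(v[length(v)] - v[1], -0.01 * 999 / 10, tolerance = 1e-12)
  # with AR(1) noise the mean residual shrinks like the effective-n CLT rate
  en <- effect_spec(temp_noise_sd_C = 0.05, temp_noise_tau_s = 1)
  sim <- synthesize_temperature(en, 0, 400, fs = 10, seed = 3)
  resid <- sim$rec$values - sim$truth$trend
  phi <- exp(-1 / (1 * 10))
  n_eff <- length(resid) * (1 - phi) / (1 + phi)
  expect_lt(abs(mean(resid)), 3 * 0.05 / sqrt(n_eff))
})

test_that("cohort simulation honours the design and is reproducible", {
  cfg <- cohort_config(n_participants = 2, tests = c("Stroop", "VisualNBack"),
                       phase_duration_s = 60, fs = 50, seed = 3)
  coh <- simulate_cohort(cfg, eff)
  expect_equal(nrow(coh$labels), 2 * 2 * 4)
  expect_length(coh$phases, 16)
  expect_true(all(coh$labels$class[coh$labels$phase == 0] == 0))
  expect_true(all(coh$labels$class[coh$labels$phase > 0] %in% 1:4))
  expect_true(all(vapply(coh$phases, function(p)
    inherits(p$ppg, "channel_recording") && inherits(p$eda, "channel_recording") &&
      inherits(p$temp, "channel_recording"), logical(1))))
  coh2 <- simulate_cohort(cfg, eff)
  expect_identical(coh$labels, coh2$labels)
  expect_identical(coh$phases[[5]]$ppg$values, coh2$phases[[5]]$ppg$values)
})

test_that("a point-mass label distribution labels every task phase class 4", {
  cfg <- cohort_config(n_participants = 3, tests = "Stroop",
                       phase_duration_s = 60, fs = 50,
                       label_distribution = c(0, 0, 0, 1), seed = 9)
  labs <- sample_cohort_labels(cfg)
  expect_true(all(labs$class[labs$phase > 0] == 4))
})

test_that("default design yields 448 phase recordings", {
  cfg <- cohort_config()
  labs <- sample_cohort_labels(cfg)
  expect_equal(nrow(labs), 28 * 4 * 4)
})

test_that("cohort round-trips through per-phase CSV files", {
  cfg <- cohort_config(n_participants = 2, tests = "Stroop",
                       phase_duration_s = 60, fs = 50, seed = 4)
  coh <- simulate_cohort(cfg, eff)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  labs <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(labs, coh$labels)
  back <- read_phase_csv(file.path(dir, "1_Stroop_0.csv"))
  expect_equal(back$ppg$fs, 50)
  expect_equal(back$eda$values, coh$phases[["1/Stroop/0"]]$eda$values,
               tolerance = 1e-6)
})
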