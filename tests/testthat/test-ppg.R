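eff <- effect_spec()

test_that("beats are recovered exactly on clean synthetic PPG", {
  ibis <- simulate_ibi_series(
    effect_spec(ibi_lf_amp_s = 0, ibi_hf_amp_s = 0, ibi_noise_sd_s = 0,
                ibi_mean_s = 0.8), 0, 60)
  p <- synthesize_ppg(ibis, eff, 0, fs = 100, noise_sd = 0)
  b <- detect_beats(p$rec)
  expect_equal(length(b$beat_times), length(p$beat_times))
  expect_true(all(abs(b$ibis - 0.8) <= 1 / 100 + 1e-9))
})

test_that("beat detection stays within 50 ms of truth at 5% noise", {
  hits <- total <- 0
  for (seed in 1:5) {
    ibis <- simulate_ibi_series(eff, 0, 120, seed = seed)
    p <- synthesize_ppg(ibis, eff, 0, fs = 100, seed = seed + 100, noise_sd = 0.05)
    b <- detect_beats(p$rec)
    errs <- vapply(p$beat_times, function(t) min(abs(b$beat_times - t)), numeric(1))
    hits <- hits + sum(errs < 0.05)
    total <- total + length(errs)
  }
  expect_gte(hits / total, 0.99)
})

test_that("median IBI recovery error stays below 10 ms at default noise", {
  errs <- unlist(lapply(1:20, function(seed) {
    ibis <- simulate_ibi_series(eff, seed %% 5, 60, seed = seed)
    p <- synthesize_ppg(ibis, eff, seed %% 5, fs = 100, seed = seed + 200)
    b <- detect_beats(p$rec)
    m <- min(length(b$ibis), length(ibis))
    abs(b$ibis[seq_len(m)] - ibis[seq_len(m)])
  }))
  expect_lt(stats::median(errs) * 1000, 10)
})

test_that("flat-line and too-short input are rejected", {
  expect_error(detect_beats(channel_recording(rep(1, 2000), 100, "ppg")),
               "insufficient beats")
  expect_error(detect_beats(channel_recording(rnorm(400), 50, "ppg")),
               "at least 10 s")
})

test_that("shape features follow hand-computed window statistics", {
  # constant morphology: zero SDs, mean = median = the constant
  b <- synthetic_beats(rep(0.8, 25), amplitudes = rep(2, 26),
                       rise_times = rep(0.12, 26))
  f <- ppg_shape_features(b, matrix(c(0, 20), 1))
  expect_equal(unname(f["ppg_amplitude_mean"]), 2)
  expect_equal(unname(f["ppg_amplitude_median"]), 2)
  expect_equal(unname(f["ppg_amplitude_sd"]), 0)
  expect_equal(unname(f["ppg_rise_time_mean"]), 0.12)
  expect_equal(unname(f["ppg_duration_mean"]), 0.8)

  # alternating amplitudes 1,2 in one window: sample SD convention
  b2 <- synthetic_beats(rep(1, 9), amplitudes = rep(c(1, 2), 5))
  f2 <- ppg_shape_features(b2, matrix(c(0, 10), 1))
  expect_equal(unname(f2["ppg_amplitude_mean"]), 1.5)
  expect_equal(unname(f2["ppg_amplitude_median"]), 1.5)
  expect_equal(unname(f2["ppg_amplitude_sd"]), sd(rep(c(1, 2), 5)))

  # two windows with window means 1 and 2 average to 1.5
  b3 <- synthetic_beats(rep(1, 19),
                        amplitudes = c(rep(1, 10), rep(2, 10)))
  f3 <- ppg_shape_features(b3, matrix(c(0, 10, 10, 20), 2))
  expect_equal(unname(f3["ppg_amplitude_mean"]), 1.5)
})

test_that("windows with fewer than two beats are skipped with a warning", {
  b <- synthetic_beats(rep(0.8, 12))
  expect_warning(f <- ppg_shape_features(b, matrix(c(0, 5, 20, 30), 2, byrow = TRUE)),
                 "skipped")
  expect_false(anyNA(f[c("ppg_amplitude_mean", "ppg_rise_time_mean")]))
})

test_that("the BPM trend interpolates 60/IBI between beats without extrapolation", {
  b <- beat_series(c(0, 0.5, 1.5, 2.5))
  tr <- bpm_trend(b, grid_hz = 4)
  expect_equal(range(tr$times), c(0, 2.5))
  expect_equal(tr$bpm[tr$times == 0.5], 120)
  expect_equal(tr$bpm[tr$times == 1.5], 60)
  b2 <- beat_series(cumsum(c(0, rep(0.8, 20))))
  expect_true(all(abs(bpm_trend(b2)$bpm - 75) < 1e-9))
})

test_that("pNN50 matches the hand-counted example and its bounds", {
  b <- beat_series(cumsum(c(0, c(800, 860, 820, 900, 905) / 1000)))
  f <- hr_hrv_features(b)
  expect_equal(unname(f["pnn50"]), 50)
  expect_equal(unname(f["bpm_mean"]) > 0, TRUE)
  for (seed in 1:5) {
    ib <- simulate_ibi_series(eff, seed %% 5, 90, seed = seed)
    fv <- hr_hrv_features(beat_series(cumsum(c(0, ib))))
    expect_gte(fv[["pnn50"]], 0); expect_lte(fv[["pnn50"]], 100)
    expect_gte(fv[["plf_mean"]], 0); expect_gte(fv[["phf_mean"]], 0)
  }
})

test_that("constant heart rate gives zero variability and negligible band power", {
  b <- beat_series(cumsum(c(0, rep(0.8, 400))))
  f <- hr_hrv_features(b)
  expect_equal(unname(f["bpm_sd"]), 0)
  expect_lt(f[["plf_mean"]], 1e-6)
  expect_lt(f[["phf_mean"]], 1e-6)
})

test_that("planted band modulation drives the PLF/PHF ratio to the right side", {
  e_hf <- effect_spec(ibi_lf_amp_s = 0, ibi_hf_amp_s = 0.05, ibi_noise_sd_s = 0.002)
  ib <- simulate_ibi_series(e_hf, 0, 300, seed = 2)
  f_hf <- hr_hrv_features(beat_series(cumsum(c(0, ib))))
  expect_lt(f_hf[["lf_hf_ratio_mean"]], 0.2)
  e_lf <- effect_spec(ibi_lf_amp_s = 0.05, ibi_hf_amp_s = 0, ibi_noise_sd_s = 0.002)
  ib <- simulate_ibi_series(e_lf, 0, 300, seed = 2)
  f_lf <- hr_hrv_features(beat_series(cumsum(c(0, ib))))
  expect_gt(f_lf[["lf_hf_ratio_mean"]], 5)
})

test_that("spectral features are flagged missing on short trends", {
  b <- beat_series(cumsum(c(0, rep(0.8, 50))))  # 40 s
  f <- hr_hrv_features(b)
  expect_true(is.na(f[["plf_mean"]]))
  expect_false(is.na(f[["bpm_mean"]]))
})

test_that("band partition: PLF + PHF equals the total 0.04-0.4 Hz power", {
  ib <- simulate_ibi_series(eff, 3, 300, seed = 8)
  tr <- bpm_trend(beat_series(cumsum(c(0, ib))))
  sg <- bpm_spectrogram(tr)
  sel_all <- sg$freq >= 0.04 & sg$freq <= 0.4
  tot <- colSums(sg$psd[sel_all, , drop = FALSE]) * sg$df
  lf <- colSums(sg$psd[sg$freq >= 0.04 & sg$freq < 0.15, , drop = FALSE]) * sg$df
  hf <- colSums(sg$psd[sg$freq >= 0.15 & sg$freq <= 0.4, , drop = FALSE]) * sg$df
  expect_equal(lf + hf, tot, tolerance = 1e-12)
})

test_that("the spectrogram localizes a pure tone and satisfies Parseval", {
  t <- seq(0, 400, by = 0.25)
  tr <- structure(list(times = t, bpm = 75 + 3 * sin(2 * pi * 0.1 * t), fs = 4),
                  class = "bpm_trend")
  sg <- bpm_spectrogram(tr)
  peak_f <- sg$freq[apply(sg$psd, 2, which.max)]
  expect_true(all(abs(peak_f - 0.1) <= sg$df))
  # Parseval: band-integrated PSD matches the Hann-weighted frame variance
  L <- 240
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  x <- tr$bpm - mean(tr$bpm)
  seg <- x[1:L]
  expect_equal(sum(sg$psd[, 1]) * sg$df, sum((w * seg)^2) / sum(w^2),
               tolerance = 0.05)
  # degenerate input: all-zero trend gives an all-zero map
  tr0 <- structure(list(times = t, bpm = rep(75, length(t)), fs = 4),
                   class = "bpm_trend")
  expect_true(all(bpm_spectrogram(tr0)$psd == 0))
  short <- structure(list(times = t[1:100], bpm = rep(75, 100), fs = 4),
                     class = "bpm_trend")
  expect_error(bpm_spectrogram(short), "too short")
})
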