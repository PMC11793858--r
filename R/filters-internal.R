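# Zero-phase IIR filtering with odd-reflection edge padding.
#
# signal::filtfilt() starts both passes from zero state, so step-like edges
# ring far into the record — fatal for slow corners (0.1 Hz high-pass) and
# for constant/tonic signals. Extending the signal by odd (point-mirrored)
# reflection continues constants and ramps exactly, so the transient decays
# inside the pad; `pad_s` should cover a few time constants of the filter's
# slowest pole (about 1.5 / f_corner for Butterworth designs).
# With `detrend = TRUE` the best-fit line is removed before filtering and
# added back after — only valid for unit-DC-gain (smoothing) filters, where
# it makes constants and ramps pass through exactly.
zp_filtfilt <- function(filt, x, fs, pad_s, detrend = FALSE) {
  b <- filt$b
  a <- filt$a
  n <- length(x)
  line <- 0
  if (detrend) {
    t <- seq_len(n)
    sl <- sum((t - mean(t)) * (x - mean(x))) / sum((t - mean(t))^2)
    line <- mean(x) + sl * (t - mean(t))
    x <- x - line
  }
  np <- min(n - 1L, max(3L * max(length(a), length(b)), round(pad_s * fs)))
  left <- 2 * x[1L] - x[(np + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(signal::Arma(b = b, a = a), c(left, x, right))
  y[(np + 1L):(np + n)] + line
}
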