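# Independent oracles used to validate the package's statistics. These are
# deliberately written from first principles (rank formulas, enumeration,
# Monte-Carlo permutation, stats::spec.pgram) and share no code with the
# implementation they check.

# Kruskal-Wallis H by the plain rank formula (tie-free inputs only).
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  n <- length(x)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  rsum <- mapply(function(a, b) sum(r[a:b]), starts, ends)
  12 / (n * (n + 1)) * sum(rsum^2 / sizes) - 3 * (n + 1)
}

# Monte-Carlo permutation p-value for H (upper tail), own H formula.
oracle_kw_perm_p <- function(groups, n_perm = 20000, seed = 42) {
  h_obs <- oracle_kw_h(groups)
  x <- unlist(groups)
  sizes <- lengths(groups)
  withr::with_seed(seed, {
    hs <- replicate(n_perm, {
      xp <- sample(x)
      oracle_kw_h(split(xp, rep(seq_along(sizes), sizes)))
    })
    (1 + sum(hs >= h_obs - 1e-12)) / (1 + n_perm)
  })
}

# Exact two-sided Mann-Whitney p by complete enumeration of the C(n1+n2, n1)
# assignments of ranks to the first group (tie-free inputs only).
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  centre <- n1 * n2 / 2
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-12)
}

# Band power from R's own periodogram (independent of the package's STFT).
oracle_band_power <- function(x, fs, lo, hi, closed_hi = FALSE) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0, detrend = TRUE,
                          plot = FALSE)
  sel <- if (closed_hi) sp$freq >= lo & sp$freq <= hi else sp$freq >= lo & sp$freq < hi
  sum(sp$spec[sel])
}

# Small effect spec tuned only for test speed at low sampling rates: higher
# SCR amplitudes are not involved; defaults otherwise.
fast_effect <- function(...) effect_spec(...)

# Build a beat series with prescribed morphology for shape-feature tests.
synthetic_beats <- function(ibis, amplitudes = NULL, rise_times = NULL) {
  bt <- cumsum(c(0, ibis))
  n <- length(bt)
  if (is.null(amplitudes)) amplitudes <- rep(1, n)
  if (is.null(rise_times)) rise_times <- rep(0.15, n)
  beat_series(bt, amplitudes = amplitudes, rise_times = rise_times)
}
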