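#' Tonic/phasic decomposition of electrodermal activity
#'
#' Splits an EDA record into a slow tonic component (skin conductance
#' level), a fast phasic component (skin conductance responses) and a
#' residual by solving the convex program
#' \deqn{\min_{q \ge 0,\, c}\; \tfrac12 \lVert y - Kq - Bc \rVert^2
#'   + \alpha \lVert q \rVert_1 + \tfrac{\gamma}{2} \lVert D^2 B c \rVert^2}
#' where \eqn{K} is convolution with the [bateman_kernel()], \eqn{q} is the
#' non-negative sparse sudomotor driver, \eqn{B} a cubic B-spline basis for
#' the tonic curve and \eqn{D^2} a second-difference (curvature) operator.
#' The program is solved by coordinate descent ([glmnet::glmnet()]) with
#' box constraints for the driver, unpenalized spline columns and the
#' curvature penalty expressed as augmented least-squares rows.
#'
#' The input is low-pass filtered and decimated to `fs_solve` before
#' solving; EDA bandwidth is far below that rate and the problem size grows
#' quadratically with it.
#'
#' @param eda A `channel_recording` of kind `"eda"`, at least 30 s long.
#' @param tau1,tau2 Bateman kernel rise/decay constants in seconds.
#' @param alpha L1 weight on the driver (sparsity), in microsiemens.
#' @param gamma Curvature penalty weight on the tonic spline.
#' @param fs_solve Solver grid rate in Hz (must be <= 25; default 8).
#' @param knot_spacing_s Tonic spline knot spacing in seconds (default 10).
#' @return An object of class `eda_decomposition`: list with `t` (s),
#'   `fs`, `tonic`, `phasic`, `driver`, `residual` (all microsiemens on the
#'   solver grid; `tonic + phasic + residual` reconstructs the decimated
#'   input exactly), `objective`, `objective_zero_driver` and `tau1`, `tau2`.
#' @export
decompose_eda <- function(eda, tau1 = 0.7, tau2 = 3.0, alpha = 0.02,
                          gamma = 10, fs_solve = 8, knot_spacing_s = 10) {
  stopifnot(inherits(eda, "channel_recording"), tau1 > 0, tau1 < tau2,
            alpha > 0, gamma >= 0)
  if (duration(eda) < 30) stop("EDA record must be at least 30 s long", call. = FALSE)
  if (fs_solve > 25) stop("`fs_solve` must be <= 25 Hz", call. = FALSE)
  y <- eda$values
  fs <- eda$fs
  if (fs > fs_solve) {
    dec <- max(1L, round(fs / fs_solve))
    if (fs / 2 > 0.4 * fs_solve) {
      lp <- signal::butter(4, min(0.9, (0.4 * fs_solve) / (fs / 2)), type = "low")
      y <- zp_filtfilt(lp, y, fs, pad_s = 1.5 / (0.4 * fs_solve), detrend = TRUE)
    }
    y <- y[seq(1L, length(y), by = dec)]
    fs <- fs / dec
  }
  n <- length(y)
  t <- (0:(n - 1L)) / fs
  k <- bateman_kernel(t, tau1, tau2)
  ij <- outer(seq_len(n), seq_len(n), "-") + 1L
  K <- matrix(0, n, n)
  pos <- ij >= 1L
  K[pos] <- k[ij[pos]]
  dur <- t[n]
  knots <- if (dur > 2 * knot_spacing_s) {
    seq(knot_spacing_s, dur - knot_spacing_s, by = knot_spacing_s)
  } else {
    NULL
  }
  B <- splines::bs(t, knots = knots, intercept = TRUE)
  B <- matrix(as.numeric(B), nrow = n)
  p <- ncol(B)
  D2B <- diff(B, differences = 2)
  Xaug <- rbind(cbind(K, B),
                cbind(matrix(0, nrow(D2B), n), sqrt(gamma) * D2B))
  yaug <- c(y, rep(0, nrow(D2B)))
  N <- length(yaug)
  lam <- alpha / N
  fit <- glmnet::glmnet(Xaug, yaug, lambda = c(lam * 25, lam * 5, lam),
                        standardize = FALSE, intercept = FALSE,
                        lower.limits = c(rep(0, n), rep(-Inf, p)),
                        penalty.factor = c(rep(1, n), rep(0, p)),
                        thresh = 1e-12, maxit = 1e6)
  beta <- as.numeric(stats::coef(fit, s = lam, exact = FALSE))[-1L]
  if (anyNA(beta)) {
    stop("EDA decomposition solver failed to converge (NA coefficients)", call. = FALSE)
  }
  q <- pmax(beta[seq_len(n)], 0)
  cc <- beta[-seq_len(n)]
  tonic <- as.numeric(B %*% cc)
  phasic <- as.numeric(K %*% q)
  residual <- y - tonic - phasic
  obj <- 0.5 * sum(residual^2) + alpha * sum(q) +
    0.5 * gamma * sum((D2B %*% cc)^2)
  # feasible reference point: zero driver, tonic = penalized LS fit
  A0 <- crossprod(B) + gamma * crossprod(D2B)
  c0 <- solve(A0, crossprod(B, y))
  r0 <- y - as.numeric(B %*% c0)
  obj0 <- 0.5 * sum(r0^2) + 0.5 * gamma * sum((D2B %*% c0)^2)
  structure(list(t = t, fs = fs, tonic = tonic, phasic = phasic, driver = q,
                 residual = residual, objective = obj,
                 objective_zero_driver = obj0, tau1 = tau1, tau2 = tau2),
            class = "eda_decomposition")
}

#' @export
print.eda_decomposition <- function(x, ...) {
  cat(sprintf("<eda_decomposition: %.0f s @ %g Hz, %d driver impulses, objective %.4g>\n",
              x$t[length(x$t)], x$fs, sum(x$driver > 1e-6), x$objective))
  invisible(x)
}

#' Write an EDA decomposition to CSV for inspection
#' @param decomp An `eda_decomposition`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decomposition_csv <- function(decomp, path) {
  stopifnot(inherits(decomp, "eda_decomposition"))
  utils::write.csv(data.frame(time_s = decomp$t, tonic = decomp$tonic,
                              phasic = decomp$phasic, driver = decomp$driver,
                              residual = decomp$residual),
                   path, row.names = FALSE)
  invisible(path)
}

#' Skin-conductance-level features
#'
#' Mean, sample standard deviation and least-squares slope of the tonic
#' component over a phase.
#'
#' @param tonic A `channel_recording`, an `eda_decomposition` (its tonic
#'   component is used), or a numeric vector (then `fs` is required).
#' @param fs Sampling rate in Hz when `tonic` is a bare numeric vector.
#' @return Named numeric vector: `scl_mean` (uS), `scl_sd` (uS),
#'   `scl_slope` (uS/s).
#' @examples
#' scl_features(2 + 0.01 * seq(0, 100, by = 0.25), fs = 4)
#' @export
scl_features <- function(tonic, fs = NULL) {
  if (inherits(tonic, "eda_decomposition")) {
    v <- tonic$tonic; fs <- tonic$fs
  } else if (inherits(tonic, "channel_recording")) {
    v <- tonic$values; fs <- tonic$fs
  } else {
    stopifnot(is.numeric(tonic), !is.null(fs))
    v <- tonic
  }
  if (length(v) < 2L) stop("need at least 2 samples", call. = FALSE)
  t <- (seq_along(v) - 1L) / fs
  slope <- sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
  c(scl_mean = mean(v), scl_sd = stats::sd(v), scl_slope = slope)
}

#' Skin-conductance-response features
#'
#' Locates SCR peaks as local maxima of the phasic component whose
#' amplitude (peak minus preceding trough) reaches `min_amp_uS`, and
#' summarizes their amplitude and rise time (trough to peak) plus the peak
#' count over the phase.
#'
#' @param decomp An `eda_decomposition`.
#' @param min_amp_uS Amplitude acceptance floor in microsiemens (default 0.01).
#' @return Named numeric vector: `scr_amplitude_mean`, `scr_amplitude_sd`
#'   (uS), `scr_rise_time_mean`, `scr_rise_time_sd` (s), `scr_count`.
#'   Amplitude and rise entries are `NA` when no peak passes the floor
#'   (`scr_count` is then 0); SD entries are `NA` with a single peak.
#' @export
scr_features <- function(decomp, min_amp_uS = 0.01) {
  stopifnot(inherits(decomp, "eda_decomposition"))
  ph <- decomp$phasic
  n <- length(ph)
  is_max <- c(FALSE, ph[2:(n - 1)] > ph[1:(n - 2)] & ph[2:(n - 1)] >= ph[3:n], FALSE)
  peaks <- which(is_max)
  amps <- numeric(0)
  rises <- numeric(0)
  prev_trough_end <- 1L
  for (pk in peaks) {
    w <- prev_trough_end:(pk - 1L)
    if (!length(w)) next
    mn <- min(ph[w])
    tr <- w[max(which(ph[w] == mn))]
    a <- ph[pk] - mn
    if (a >= min_amp_uS) {
      amps <- c(amps, a)
      rises <- c(rises, (pk - tr) / decomp$fs)
      prev_trough_end <- pk
    }
  }
  cnt <- length(amps)
  c(scr_amplitude_mean = if (cnt) mean(amps) else NA_real_,
    scr_amplitude_sd = if (cnt > 1L) stats::sd(amps) else NA_real_,
    scr_rise_time_mean = if (cnt) mean(rises) else NA_real_,
    scr_rise_time_sd = if (cnt > 1L) stats::sd(rises) else NA_real_,
    scr_count = cnt)
}
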