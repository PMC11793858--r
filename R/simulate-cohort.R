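# Deterministic sub-seed derivation: doubles are exact below 2^53, so the
# modular arithmetic here is exact; results stay in [0, 2^31).
derive_seed <- function(seed, ...) {
  ix <- c(...)
  h <- (seed %% 2147483647) + 1
  for (k in ix) h <- (h * 48271 + k) %% 2147483647
  as.integer(h)
}

#' Simulate a full multimodal cohort
#'
#' Generates the complete study design: `n_participants` subjects, each
#' performing every test in `config$tests`, each test split into one rest
#' phase (class 0) followed by task sub-phases whose class labels (1-4) are
#' drawn from the per-test label distribution. Every phase carries three
#' synchronized channels (PPG, EDA, skin temperature) synthesized by
#' [synthesize_ppg()], [synthesize_eda()] and [synthesize_temperature()]
#' with the class effects of `effect`, plus per-phase ground truth.
#'
#' The whole cohort is reproducible from `config$seed`; every phase and
#' channel uses an independently derived sub-seed.
#'
#' @param config A [cohort_config()].
#' @param effect An [effect_spec()].
#' @return An object of class `cohort_recording`: a list with
#'   \describe{
#'     \item{labels}{data.frame `(subject, test, phase, class)`, one row per
#'       phase; phase 0 is always class 0.}
#'     \item{phases}{named list (key `"subject/test/phase"`) of lists with
#'       elements `ppg`, `eda`, `temp` (`channel_recording`s) and `truth`
#'       (beat times, SCR events, tonic and temperature trends).}
#'     \item{config, effect}{the inputs, for provenance.}
#'   }
#' @examples
#' cfg <- cohort_config(n_participants = 2, tests = "Stroop",
#'                      phase_duration_s = 60, fs = 100, seed = 7)
#' coh <- simulate_cohort(cfg, effect_spec())
#' table(coh$labels$class)
#' @export
simulate_cohort <- function(config, effect = effect_spec()) {
  stopifnot(inherits(config, "cohort_config"), inherits(effect, "effect_spec"))
  labels <- sample_cohort_labels(config)
  phases <- vector("list", nrow(labels))
  names(phases) <- with(labels, paste(subject, test, phase, sep = "/"))
  for (r in seq_len(nrow(labels))) {
    s <- labels$subject[r]; tn <- labels$test[r]; ph <- labels$phase[r]
    cls <- labels$class[r]
    ti <- match(tn, config$tests)
    base <- c(s, ti, ph)
    ibis <- simulate_ibi_series(effect, cls, config$phase_duration_s,
                                seed = derive_seed(config$seed, base, 1L))
    ppg <- synthesize_ppg(ibis, effect, cls, config$fs,
                          seed = derive_seed(config$seed, base, 2L))
    eda <- synthesize_eda(effect, cls, config$phase_duration_s, config$fs,
                          seed = derive_seed(config$seed, base, 3L))
    tmp <- synthesize_temperature(effect, cls, config$phase_duration_s, config$fs,
                                  seed = derive_seed(config$seed, base, 4L))
    # align channel lengths: PPG synthesis runs past the phase end to finish
    # the last pulse; all channels are cut to the phase grid
    n_phase <- round(config$phase_duration_s * config$fs)
    trim <- function(rec) {
      channel_recording(rec$values[seq_len(min(n_phase, length(rec$values)))],
                        rec$fs, rec$kind, rec$t0)
    }
    phases[[r]] <- list(
      ppg = trim(ppg$rec), eda = trim(eda$rec), temp = trim(tmp$rec),
      truth = list(beat_times = ppg$beat_times, ibis = ibis,
                   scr_event_times = eda$truth$scr_event_times,
                   scr_event_amplitudes = eda$truth$scr_event_amplitudes,
                   tonic_curve = eda$truth$tonic_curve,
                   temp_trend = tmp$truth$trend,
                   class = cls))
  }
  structure(list(labels = labels, phases = phases,
                 config = config, effect = effect),
            class = "cohort_recording")
}

#' @export
print.cohort_recording <- function(x, ...) {
  cat(sprintf("<cohort_recording: %d subjects, %d tests, %d phase recordings>\n",
              x$config$n_participants, length(x$config$tests), length(x$phases)))
  invisible(x)
}

#' Sample the label table for a cohort design
#'
#' Phase 0 of every (subject, test) is the rest phase and is labeled class 0
#' exactly once; the remaining phases draw classes 1-4 from the test's label
#' distribution. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return data.frame with columns `subject`, `test`, `phase`, `class`.
#' @export
sample_cohort_labels <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- expand.grid(phase = 0:(config$n_phases - 1L),
                      test = config$tests,
                      subject = seq_len(config$n_participants),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("subject", "test", "phase")]
  grid <- grid[order(grid$subject, match(grid$test, config$tests), grid$phase), ]
  rownames(grid) <- NULL
  grid$class <- 0L
  for (tn in config$tests) {
    sel <- grid$test == tn & grid$phase > 0L
    p <- config$label_distribution[[tn]]
    grid$class[sel] <- withr::with_seed(
      derive_seed(config$seed, match(tn, config$tests), 999L),
      sample(1:4, sum(sel), replace = TRUE, prob = p))
  }
  grid
}

#' Write a simulated cohort to disk
#'
#' One CSV per phase (columns `time_s, ppg, eda_uS, temp_C`) with a YAML
#' sidecar carrying the sampling rate, plus `labels.csv` with the
#' (subject, test, phase, class) table.
#'
#' @param cohort A `cohort_recording`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  for (key in names(cohort$phases)) {
    ph <- cohort$phases[[key]]
    fname <- file.path(dir, paste0(gsub("/", "_", key), ".csv"))
    write_phase_csv(ph$ppg, ph$eda, ph$temp, fname,
                    metadata = list(id = key, class = ph$truth$class))
  }
  invisible(dir)
}

#' Simulate a labeled feature table directly (no signal synthesis)
#'
#' Draws per-phase feature values at the feature level rather than through
#' full signal synthesis and extraction; this is the generator used for
#' statistical validation of the screening stage (null false-discovery-rate
#' studies and planted-effect power studies), where hundreds of cohort
#' replicates are needed.
#'
#' Each (subject, test, phase, feature) raw value is drawn
#' \eqn{N(\delta_f \cdot c, 1)}, where `c` is the phase's class label and
#' \eqn{\delta_f} is the per-class shift (in pooled-SD units, since the
#' within-class SD is 1) for features named in `shifted_features` — zero for
#' all others. Values are then max-min normalized per subject, test and
#' feature via [minmax_normalize()].
#'
#' @param config A [cohort_config()]; only the design counts and label
#'   distribution are used.
#' @param shifted_features Character vector of features given a class shift.
#' @param shift_per_class Shift per unit class (pooled-SD units); class `c`
#'   is shifted by `shift_per_class * c`. Default 0 (global null).
#' @param features Feature name catalogue (default [feature_catalogue()]).
#' @param seed Overrides `config$seed` when non-NULL.
#' @return A normalized `feature_table` (see [assemble_dataset()]).
#' @export
simulate_feature_table <- function(config = cohort_config(),
                                   shifted_features = character(),
                                   shift_per_class = 0,
                                   features = feature_catalogue(),
                                   seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!all(shifted_features %in% features)) {
    stop("`shifted_features` must be a subset of the feature catalogue", call. = FALSE)
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  labels <- sample_cohort_labels(config)
  nf <- length(features)
  values <- withr::with_seed(derive_seed(config$seed, 77L), {
    long <- labels[rep(seq_len(nrow(labels)), each = nf), ]
    long$feature <- rep(features, times = nrow(labels))
    shift <- ifelse(long$feature %in% shifted_features,
                    shift_per_class * long$class, 0)
    long$value <- stats::rnorm(nrow(long), mean = shift, sd = 1)
    long
  })
  rownames(values) <- NULL
  tbl <- assemble_dataset(values[, c("subject", "test", "phase", "feature", "value")],
                          labels, catalogue = features)
  minmax_normalize(tbl)
}
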