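#' Uniformly sampled signal channel
#'
#' The basic container used throughout the package: one channel of a
#' physiological recording, sampled on a uniform grid.
#'
#' @param values Numeric vector of samples.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param kind Channel kind, one of `"ppg"`, `"eda"`, `"temp"`, or a free
#'   string for derived series (e.g. `"temp_derivative"`).
#' @param t0 Time of the first sample in seconds (default 0); segments cut
#'   from a longer record keep their original clock.
#'
#' @return An object of class `channel_recording`: a list with elements
#'   `values`, `fs`, `kind`, `t0`.
#' @examples
#' rec <- channel_recording(sin(2 * pi * seq(0, 1, by = 0.01)), fs = 100, kind = "ppg")
#' duration(rec)
#' @export
channel_recording <- function(values, fs, kind = "signal", t0 = 0) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar sampling rate in Hz", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs),
         kind = as.character(kind), t0 = as.numeric(t0)),
    class = "channel_recording"
  )
}

#' @export
print.channel_recording <- function(x, ...) {
  cat(sprintf("<channel_recording: %s, %d samples @ %g Hz, %.1f s>\n",
              x$kind, length(x$values), x$fs, duration(x)))
  invisible(x)
}

#' Duration of a channel recording in seconds
#' @param rec A `channel_recording`.
#' @return Length of the record in seconds (`n / fs`).
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "channel_recording"))
  length(rec$values) / rec$fs
}

#' Sample times of a channel recording
#' @param rec A `channel_recording`.
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(rec) {
  stopifnot(inherits(rec, "channel_recording"))
  rec$t0 + (seq_along(rec$values) - 1L) / rec$fs
}

#' Write one phase of a multichannel recording to CSV with a YAML sidecar
#'
#' Writes columns `time_s, ppg, eda_uS, temp_C` and a `<path>.yaml` sidecar
#' holding the sampling rate and any extra metadata.
#'
#' @param ppg,eda,temp `channel_recording` objects sharing `fs` and length.
#' @param path Output CSV path.
#' @param metadata Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_phase_csv <- function(ppg, eda, temp, path, metadata = list()) {
  stopifnot(inherits(ppg, "channel_recording"),
            inherits(eda, "channel_recording"),
            inherits(temp, "channel_recording"))
  if (length(unique(c(ppg$fs, eda$fs, temp$fs))) != 1L ||
      length(unique(lengths(list(ppg$values, eda$values, temp$values)))) != 1L) {
    stop("channels must share sampling rate and length", call. = FALSE)
  }
  df <- data.frame(time_s = sample_times(ppg), ppg = ppg$values,
                   eda_uS = eda$values, temp_C = temp$values)
  utils::write.csv(df, path, row.names = FALSE)
  side <- c(list(fs = ppg$fs, n_samples = length(ppg$values)), metadata)
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(side, paste0(path, ".yaml"))
  } else {
    writeLines(paste(names(side), unlist(side), sep = ": "), paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Read a phase CSV written by [write_phase_csv()]
#'
#' @param path CSV path; the `<path>.yaml` sidecar supplies `fs` (falls back
#'   to the median time step if the sidecar is missing).
#' @return Named list of `channel_recording`s: `ppg`, `eda`, `temp`.
#' @export
read_phase_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "ppg", "eda_uS", "temp_C")
  if (!all(need %in% names(df))) {
    stop("phase CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  side <- paste0(path, ".yaml")
  fs <- if (file.exists(side) && requireNamespace("yaml", quietly = TRUE)) {
    as.numeric(yaml::read_yaml(side)$fs)
  } else {
    1 / stats::median(diff(df$time_s))
  }
  t0 <- df$time_s[1L]
  list(ppg  = channel_recording(df$ppg, fs, "ppg", t0),
       eda  = channel_recording(df$eda_uS, fs, "eda", t0),
       temp = channel_recording(df$temp_C, fs, "temp", t0))
}
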