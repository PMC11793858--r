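#' Assemble labeled per-test feature tables
#'
#' Joins per-phase feature values with the (subject, test, phase) class
#' labels into one long `feature_table` covering the complete design grid:
#' per test, exactly `n_participants x n_phases x n_features` rows. Missing
#' feature values are kept as explicitly flagged `NA` rows, so the
#' row-count identity holds regardless of extraction failures.
#'
#' @param features data.frame with columns `subject`, `test`, `phase`,
#'   `feature`, `value` (one row per phase per feature); values for
#'   features outside the catalogue are an error.
#' @param labels data.frame with columns `subject`, `test`, `phase`,
#'   `class`; every (subject, test, phase) present in `features` must be
#'   labeled, phase 0 with class 0.
#' @param catalogue Character vector of feature names defining the table
#'   grid; defaults to [feature_catalogue()].
#' @return An object of class `feature_table`: a data.frame with columns
#'   `subject`, `test`, `phase`, `class`, `feature`, `value`,
#'   `normalized_value` (`NA` until [minmax_normalize()]), `missing`,
#'   `degenerate`, plus attributes `n_participants`, `n_phases`,
#'   `n_features`, `tests`, `normalized`.
#' @examples
#' f <- expand.grid(subject = 1:2, test = "Stroop", phase = 0:3,
#'                  feature = c("a", "b", "c"), stringsAsFactors = FALSE)
#' f$value <- rnorm(nrow(f))
#' l <- unique(f[, c("subject", "test", "phase")])
#' l$class <- ifelse(l$phase == 0, 0L, 2L)
#' tbl <- assemble_dataset(f, l, features = c("a", "b", "c"))
#' nrow(tbl)  # 2 * 4 * 3 = 24
#' @export
assemble_dataset <- function(features, labels, catalogue = feature_catalogue()) {
  need_f <- c("subject", "test", "phase", "feature", "value")
  need_l <- c("subject", "test", "phase", "class")
  stopifnot(all(need_f %in% names(features)), all(need_l %in% names(labels)))
  bad <- setdiff(unique(features$feature), catalogue)
  if (length(bad)) {
    stop("features outside the catalogue: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  key_f <- with(features, paste(subject, test, phase, sep = "\r"))
  key_l <- with(labels, paste(subject, test, phase, sep = "\r"))
  unlabeled <- setdiff(unique(key_f), key_l)
  if (length(unlabeled)) {
    stop("missing class label for (subject, test, phase) = (",
         gsub("\r", ", ", unlabeled[1L]), ")", call. = FALSE)
  }
  dup <- duplicated(paste(key_f, features$feature, sep = "\r"))
  if (any(dup)) {
    d <- features[dup, ][1L, ]
    stop(sprintf("duplicate feature row: subject %s, test %s, phase %s, feature %s",
                 d$subject, d$test, d$phase, d$feature), call. = FALSE)
  }
  if (any(labels$class[labels$phase == 0] != 0)) {
    stop("phase 0 must carry class 0 (rest baseline)", call. = FALSE)
  }
  n0 <- stats::aggregate(class ~ subject + test, labels, function(z) sum(z == 0))
  if (any(n0$class != 1L)) {
    stop("each (subject, test) must have exactly one class-0 phase", call. = FALSE)
  }
  subjects <- sort(unique(labels$subject))
  tests <- unique(labels$test)
  phases <- sort(unique(labels$phase))
  grid <- expand.grid(feature = catalogue, phase = phases, test = tests,
                      subject = subjects,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("subject", "test", "phase", "feature")]
  grid <- grid[order(grid$subject, match(grid$test, tests), grid$phase,
                     match(grid$feature, catalogue)), ]
  rownames(grid) <- NULL
  kg <- with(grid, paste(subject, test, phase, feature, sep = "\r"))
  kf <- paste(key_f, features$feature, sep = "\r")
  grid$value <- features$value[match(kg, kf)]
  grid$class <- labels$class[match(with(grid, paste(subject, test, phase, sep = "\r")),
                                   key_l)]
  grid$normalized_value <- NA_real_
  grid$missing <- is.na(grid$value)
  grid$degenerate <- FALSE
  grid <- grid[, c("subject", "test", "phase", "class", "feature", "value",
                   "normalized_value", "missing", "degenerate")]
  structure(grid,
            n_participants = length(subjects), n_phases = length(phases),
            n_features = length(catalogue), tests = tests, normalized = FALSE,
            class = c("feature_table", "data.frame"))
}

#' Per-subject max-min normalization
#'
#' For every (subject, test, feature) the phase values are rescaled to
#' \eqn{v' = (v - \min v) / (\max v - \min v)} over that subject's phases
#' within that test dataset, mapping each subject's own range onto [0, 1].
#' Features constant across a subject's phases map to 0 and are flagged
#' `degenerate`. The transform is invariant to positive affine changes of
#' the raw scale.
#'
#' @param table A `feature_table` from [assemble_dataset()].
#' @return The table with `normalized_value` filled in and attribute
#'   `normalized = TRUE`.
#' @export
minmax_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  key <- with(table, paste(subject, test, feature, sep = "\r"))
  lo <- stats::ave(table$value, key, FUN = function(v) {
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  })
  hi <- stats::ave(table$value, key, FUN = function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  rng <- hi - lo
  degen <- !is.na(rng) & rng == 0
  out <- ifelse(degen, 0, (table$value - lo) / rng)
  table$normalized_value <- out
  table$degenerate <- degen & !is.na(table$value)
  attr(table, "normalized") <- TRUE
  table
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d rows (%d subjects x %d phases x %d features x %d tests)%s>\n",
              nrow(x), attr(x, "n_participants"), attr(x, "n_phases"),
              attr(x, "n_features"), length(attr(x, "tests")),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

#' Split a feature table by test dataset
#' @param table A `feature_table`.
#' @return Named list of per-test `feature_table`s (attributes preserved,
#'   `tests` reduced to the single test).
#' @export
split_by_test <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  lapply(stats::setNames(nm = attr(table, "tests")), function(tn) {
    sub <- table[table$test == tn, ]
    rownames(sub) <- NULL
    attributes(sub)[c("n_participants", "n_phases", "n_features", "normalized")] <-
      attributes(table)[c("n_participants", "n_phases", "n_features", "normalized")]
    attr(sub, "tests") <- tn
    class(sub) <- c("feature_table", "data.frame")
    sub
  })
}

#' Write / read a feature table as CSV with a YAML sidecar
#'
#' @param table A `feature_table`.
#' @param path CSV path; metadata goes to `<path>.yaml`.
#' @return `path` invisibly (write); a `feature_table` (read).
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- list(n_participants = attr(table, "n_participants"),
               n_phases = attr(table, "n_phases"),
               n_features = attr(table, "n_features"),
               tests = attr(table, "tests"),
               normalized = isTRUE(attr(table, "normalized")))
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(meta, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject", "test", "phase", "class", "feature", "value",
            "normalized_value")
  if (!all(need %in% names(df))) {
    stop("feature-table CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$missing)) df$missing <- is.na(df$value)
  if (is.null(df$degenerate)) df$degenerate <- FALSE
  structure(df,
            n_participants = length(unique(df$subject)),
            n_phases = length(unique(df$phase)),
            n_features = length(unique(df$feature)),
            tests = unique(df$test),
            normalized = !all(is.na(df$normalized_value)),
            class = c("feature_table", "data.frame"))
}
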