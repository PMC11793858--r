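#' Kruskal-Wallis rank test across class populations
#'
#' Computes the tie-corrected (mid-rank) Kruskal-Wallis H statistic. The
#' p-value comes from the chi-square approximation with k-1 degrees of
#' freedom (`method = "chisq"`, the convention for cohort-sized groups) or
#' from a Monte-Carlo permutation of the group labels
#' (`method = "permutation"`), which is preferable for very small groups
#' where the chi-square approximation is inaccurate.
#'
#' @param groups List of >= 2 non-empty numeric samples.
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Number of Monte-Carlo permutations (permutation method).
#' @param perm_seed Seed for the permutation draw.
#' @return A `test_result`: list with `statistic` (H), `p_value`,
#'   `group_sizes`, `ties` (whether a tie correction was applied) and
#'   `method`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))$statistic  # 32/7
#' @export
kruskal_wallis <- function(groups, method = c("chisq", "permutation"),
                           n_perm = 10000, perm_seed = 1L) {
  method <- match.arg(method)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("all groups must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (sum(sizes) < 5L) {
    warning("fewer than 5 observations: the chi-square approximation is unreliable",
            call. = FALSE)
  }
  kt <- stats::kruskal.test(x, g)
  h <- unname(kt$statistic)
  ties <- anyDuplicated(x) > 0L
  if (all(x == x[1L])) h <- 0   # fully tied input: kruskal.test returns NaN
  p <- if (method == "chisq") {
    if (all(x == x[1L])) 1 else unname(kt$p.value)
  } else {
    h_perm <- withr::with_seed(perm_seed, {
      vapply(seq_len(n_perm), function(i) {
        ki <- stats::kruskal.test(sample(x), g)$statistic
        if (is.nan(ki)) 0 else unname(ki)
      }, numeric(1))
    })
    (1 + sum(h_perm >= h - 1e-12)) / (1 + n_perm)
  }
  structure(list(statistic = h, p_value = p, group_sizes = as.integer(sizes),
                 ties = ties, method = method, test = "kruskal-wallis"),
            class = "test_result")
}

#' Mann-Whitney U two-sample rank test
#'
#' Two-sided test of stochastic equality. With both samples at most
#' `exact_threshold` and no ties, the p-value is the exact enumeration over
#' rank assignments; otherwise the normal approximation with mid-rank tie
#' correction and continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_threshold Largest per-group size for the exact path
#'   (default 8).
#' @param force Force `"exact"` or `"approx"` regardless of size
#'   (`NULL` = automatic; exact is still refused in the presence of ties).
#' @return A `test_result`: list with `statistic` (U of `x`), `u_other`
#'   (U of `y`; the two sum to `n1 * n2`), `p_value`, `group_sizes`,
#'   `ties`, `exact`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 8, force = NULL) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- if (is.null(force)) {
    length(x) <= exact_threshold && length(y) <= exact_threshold && !ties
  } else {
    identical(force, "exact") && !ties
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided"))
  u <- unname(wt$statistic)
  p <- min(1, unname(wt$p.value))
  if (ties && all(c(x, y) == c(x, y)[1L])) p <- 1   # identical constants
  structure(list(statistic = u, u_other = length(x) * length(y) - u,
                 p_value = p, group_sizes = c(length(x), length(y)),
                 ties = ties, exact = exact, test = "mann-whitney"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g, p = %.4g, n = (%s)%s>\n",
              x$test, x$statistic, x$p_value,
              paste(x$group_sizes, collapse = ", "),
              if (isTRUE(x$ties)) ", ties" else ""))
  invisible(x)
}

#' Benjamini-Hochberg step-up correction
#'
#' Sorts the raw p-values ascending, finds the largest i with
#' `p(i) <= i * q / m`, and rejects hypotheses 1..i. Adjusted p-values are
#' the standard step-up values (monotone in raw rank); rejection is
#' equivalent to `adjusted <= q`.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param q Target false discovery rate (default 0.05).
#' @return List with `reject` (logical), `adjusted` (numeric), `q`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04), q = 0.05)$reject
#' @export
bh_adjust <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE), q > 0, q < 1)
  adj <- stats::p.adjust(p_values, method = "BH")
  list(reject = !is.na(adj) & adj <= q, adjusted = adj, q = q)
}

#' Screening configuration
#'
#' @param mode `"BA"` (binary analysis: class 0 against each altered class,
#'   4 pairs) or `"OA"` (overall analysis: all 10 class pairs).
#' @param alpha_kw Kruskal-Wallis significance level (default 0.05).
#' @param fdr_q Benjamini-Hochberg false discovery rate (default 0.05).
#' @param exact_threshold Largest per-group n for exact Mann-Whitney.
#' @param bh_scope `"per_feature"` (default: BH within each feature's
#'   family of pairwise p-values) or `"pooled"` (one family across all
#'   features and pairs).
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(mode = c("BA", "OA"), alpha_kw = 0.05,
                             fdr_q = 0.05, exact_threshold = 8,
                             bh_scope = c("per_feature", "pooled")) {
  mode <- match.arg(mode)
  bh_scope <- match.arg(bh_scope)
  stopifnot(alpha_kw > 0, alpha_kw < 1, fdr_q > 0, fdr_q < 1)
  structure(list(mode = mode, alpha_kw = alpha_kw, fdr_q = fdr_q,
                 exact_threshold = exact_threshold, bh_scope = bh_scope),
            class = "screening_config")
}

class_pairs <- function(mode) {
  if (mode == "BA") {
    cbind(0L, 1:4)
  } else {
    t(utils::combn(0:4, 2L))
  }
}

#' Run the two-tier nonparametric screening on a feature table
#'
#' For each feature of one test dataset: (i) a Kruskal-Wallis test across
#' the populated class distributions of the normalized values; (ii)
#' pairwise Mann-Whitney U tests over the mode's class pairs — class 0
#' against each altered class in binary analysis (BA), all pairs in overall
#' analysis (OA); (iii) Benjamini-Hochberg correction over the pairwise
#' family at rate `fdr_q`. Pairs in which either class has fewer than 2
#' observations are skipped and logged.
#'
#' @param table A normalized `feature_table` restricted to one test (see
#'   [split_by_test()]); with several tests present, one report per test is
#'   returned as a named list.
#' @param config A [screening_config()].
#' @return An object of class `screening_report`: list with `test` (name),
#'   `mode`, `config`, `features` (per-feature list: `kw` result, `pairs`
#'   data.frame with raw and adjusted p-values and decisions,
#'   `n_significant_pairs`), `skipped` (log of skipped comparisons) and the
#'   [significance_counts()] summary.
#' @export
run_screening <- function(table, config = screening_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "screening_config"))
  tests <- attr(table, "tests")
  if (length(tests) > 1L) {
    return(lapply(split_by_test(table), run_screening, config = config))
  }
  if (!isTRUE(attr(table, "normalized"))) {
    stop("run `minmax_normalize()` before screening", call. = FALSE)
  }
  if (length(unique(table$class)) < 2L) {
    stop("need at least 2 populated classes", call. = FALSE)
  }
  pairs <- class_pairs(config$mode)
  feats <- unique(table$feature)
  skipped <- list()
  results <- vector("list", length(feats))
  names(results) <- feats
  for (f in feats) {
    sub <- table[table$feature == f & !is.na(table$normalized_value), ]
    by_class <- split(sub$normalized_value, factor(sub$class, levels = 0:4))
    pop <- by_class[lengths(by_class) > 0L]
    kw <- if (length(pop) >= 2L) kruskal_wallis(pop) else NULL
    pr <- data.frame(class_a = pairs[, 1L], class_b = pairs[, 2L],
                     u = NA_real_, p = NA_real_)
    for (i in seq_len(nrow(pairs))) {
      a <- by_class[[as.character(pairs[i, 1L])]]
      b <- by_class[[as.character(pairs[i, 2L])]]
      if (length(a) < 2L || length(b) < 2L) {
        skipped[[length(skipped) + 1L]] <-
          sprintf("feature %s: pair %d vs %d skipped (class sizes %d, %d)",
                  f, pairs[i, 1L], pairs[i, 2L], length(a), length(b))
        next
      }
      mw <- mann_whitney_u(a, b, exact_threshold = config$exact_threshold)
      pr$u[i] <- mw$statistic
      pr$p[i] <- mw$p_value
    }
    if (config$bh_scope == "per_feature") {
      done <- !is.na(pr$p)
      pr$p_adj <- NA_real_
      pr$significant <- FALSE
      if (any(done)) {
        bh <- bh_adjust(pr$p[done], config$fdr_q)
        pr$p_adj[done] <- bh$adjusted
        pr$significant[done] <- bh$reject
      }
    } else {
      pr$p_adj <- NA_real_
      pr$significant <- NA
    }
    results[[f]] <- list(kw = kw, pairs = pr,
                         n_significant_pairs = NA_integer_)
  }
  if (config$bh_scope == "pooled") {
    all_p <- unlist(lapply(results, function(r) r$pairs$p))
    done <- !is.na(all_p)
    adj <- rep(NA_real_, length(all_p)); rej <- rep(FALSE, length(all_p))
    if (any(done)) {
      bh <- bh_adjust(all_p[done], config$fdr_q)
      adj[done] <- bh$adjusted; rej[done] <- bh$reject
    }
    off <- 0L
    for (f in feats) {
      np <- nrow(results[[f]]$pairs)
      results[[f]]$pairs$p_adj <- adj[off + seq_len(np)]
      results[[f]]$pairs$significant <- rej[off + seq_len(np)]
      off <- off + np
    }
  }
  for (f in feats) {
    results[[f]]$n_significant_pairs <-
      sum(results[[f]]$pairs$significant, na.rm = TRUE)
  }
  report <- structure(list(test = tests, mode = config$mode, config = config,
                           features = results, skipped = skipped),
                      class = "screening_report")
  report$summary <- significance_counts(report)
  if (length(skipped)) {
    for (msg in skipped) message(msg)
  }
  report
}

#' Significance-count summary of a screening report
#'
#' `test_significance` counts features whose Kruskal-Wallis p-value is
#' below `alpha_kw`; `feature_significance_gt_n` counts features
#' significant (after BH) in more than n pairwise comparisons, i.e. in at
#' least n+1 of them, for n = 1 .. (number of pairs - 1).
#'
#' @param report A `screening_report`.
#' @param alpha_kw Kruskal-Wallis threshold; defaults to the report's.
#' @return data.frame with columns `row` (label) and `count`.
#' @export
significance_counts <- function(report, alpha_kw = NULL) {
  stopifnot(inherits(report, "screening_report"))
  if (is.null(alpha_kw)) alpha_kw <- report$config$alpha_kw
  kw_p <- vapply(report$features, function(r) {
    if (is.null(r$kw)) NA_real_ else r$kw$p_value
  }, numeric(1))
  nsig <- vapply(report$features, function(r) r$n_significant_pairs, numeric(1))
  n_pairs <- nrow(class_pairs(report$mode))
  rows <- data.frame(row = "test_significance",
                     count = sum(kw_p < alpha_kw, na.rm = TRUE))
  for (n in seq_len(n_pairs - 1L)) {
    rows <- rbind(rows, data.frame(row = sprintf("feature_significance_gt_%d", n),
                                   count = sum(nsig > n)))
  }
  rows
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report: test %s, mode %s, %d features>\n",
              x$test, x$mode, length(x$features)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cross-test bullet matrix of consistently significant features
#'
#' A feature is "bulleted" for a test when its binary-analysis screening
#' found it significant (BH-adjusted) in all four class-0 comparisons; the
#' common list collects features bulleted in every test.
#'
#' @param reports List of BA-mode `screening_report`s, one per test.
#' @return List with `matrix` (features x tests logical) and
#'   `common_features` (character).
#' @export
bullet_matrix <- function(reports) {
  stopifnot(length(reports) >= 1L)
  for (r in reports) {
    stopifnot(inherits(r, "screening_report"))
    if (r$mode != "BA") stop("bullet matrix requires BA-mode reports", call. = FALSE)
  }
  feats <- names(reports[[1L]]$features)
  for (r in reports[-1L]) {
    if (!identical(sort(names(r$features)), sort(feats))) {
      stop("reports have mismatched feature sets", call. = FALSE)
    }
  }
  n_pairs <- nrow(class_pairs("BA"))
  m <- vapply(reports, function(r) {
    vapply(r$features[feats], function(fr) {
      sum(fr$pairs$significant, na.rm = TRUE) == n_pairs
    }, logical(1))
  }, logical(length(feats)))
  m <- matrix(m, nrow = length(feats),
              dimnames = list(feats, vapply(reports, `[[`, "", "test")))
  list(matrix = m, common_features = feats[rowSums(m) == ncol(m)])
}

#' Render a Table-1-style summary across tests
#'
#' @param reports Named list of `screening_report`s (same mode).
#' @return data.frame: one row per summary line, one column per test.
#' @export
summary_table <- function(reports) {
  stopifnot(length(reports) >= 1L)
  cols <- lapply(reports, function(r) r$summary$count)
  out <- data.frame(row = reports[[1L]]$summary$row)
  for (i in seq_along(reports)) out[[reports[[i]]$test]] <- cols[[i]]
  out
}
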