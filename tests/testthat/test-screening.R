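test_that("Kruskal-Wallis H matches the rank-formula value and degenerate cases", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 32 / 7)
  expect_equal(r$group_sizes, c(2L, 2L, 2L))
  rc <- suppressWarnings(kruskal_wallis(list(c(3, 3), c(3, 3))))
  expect_equal(rc$statistic, 0)
  expect_equal(rc$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("permutation Kruskal-Wallis p agrees with an independent oracle", {
  for (seed in 1:4) {
    groups <- withr::with_seed(seed, split(rnorm(15), rep(1:3, each = 5)))
    mine <- kruskal_wallis(groups, method = "permutation", n_perm = 4000,
                           perm_seed = seed + 500)$p_value
    orac <- oracle_kw_perm_p(groups, n_perm = 4000, seed = seed + 900)
    se <- sqrt(orac * (1 - orac) / 4000)
    expect_lt(abs(mine - orac), 3 * (se + sqrt(mine * (1 - mine) / 4000)) + 1e-6)
  }
})

test_that("Mann-Whitney exact p matches complete enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)
  for (seed in 1:6) {
    xy <- withr::with_seed(seed, list(x = rnorm(4 + seed %% 3), y = rnorm(5)))
    mine <- mann_whitney_u(xy$x, xy$y)$p_value
    expect_equal(mine, oracle_mw_exact_p(xy$x, xy$y), tolerance = 1e-12)
  }
})

test_that("the two Mann-Whitney statistics always sum to n1*n2", {
  for (seed in 1:10) {
    xy <- withr::with_seed(seed, list(x = rnorm(7), y = rnorm(11)))
    r <- mann_whitney_u(xy$x, xy$y)
    expect_equal(r$statistic + r$u_other, 7 * 11)
  }
})

test_that("identical samples give p = 1 under the tie convention", {
  r <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$p_value, 1)
  expect_true(r$ties)
})

test_that("normal-approximation and exact Mann-Whitney p agree within 0.02", {
  for (seed in 1:20) {
    xy <- withr::with_seed(seed + 40, list(x = rnorm(8), y = rnorm(8, seed %% 3)))
    pe <- mann_whitney_u(xy$x, xy$y, force = "exact")$p_value
    pa <- mann_whitney_u(xy$x, xy$y, force = "approx")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("two-group Kruskal-Wallis ranks datasets like Mann-Whitney", {
  ps <- t(vapply(1:30, function(seed) {
    xy <- withr::with_seed(seed, list(x = rnorm(8), y = rnorm(8, (seed %% 4) / 2)))
    c(kw = kruskal_wallis(list(xy$x, xy$y))$p_value,
      mw = mann_whitney_u(xy$x, xy$y, force = "approx")$p_value)
  }, numeric(2)))
  expect_equal(cor(rank(ps[, "kw"]), rank(ps[, "mw"]), method = "spearman"), 1,
               tolerance = 0.01)
})

test_that("Benjamini-Hochberg step-up matches its defining rule", {
  expect_true(all(bh_adjust(c(0.01, 0.02, 0.03, 0.04), 0.05)$reject))
  expect_false(any(bh_adjust(c(0.9, 0.95), 0.05)$reject))
  expect_true(bh_adjust(0.04, 0.05)$reject)   # m = 1 reduces to the raw test
  # never more rejections than uncorrected testing at the same threshold
  for (seed in 1:10) {
    p <- withr::with_seed(seed, runif(20)^2)
    bh <- bh_adjust(p, 0.05)
    expect_lte(sum(bh$reject), sum(p <= 0.05))
    expect_true(all(diff(sort(bh$adjusted)) >= -1e-12))
  }
})

test_that("screening produces the right pair families and counts", {
  tbl <- simulate_feature_table(cohort_config(n_participants = 10, tests = "Stroop",
                                              seed = 5))
  rep_ba <- run_screening(tbl, screening_config(mode = "BA"))
  rep_oa <- run_screening(tbl, screening_config(mode = "OA"))
  expect_equal(nrow(rep_ba$features[[1]]$pairs), 4)
  expect_equal(nrow(rep_oa$features[[1]]$pairs), 10)
  expect_true(all(rep_ba$features[[1]]$pairs$class_a == 0))
  expect_equal(length(rep_ba$features), 43)
  expect_equal(rep_ba$summary$row[1], "test_significance")
  expect_equal(nrow(rep_ba$summary), 4)   # KW + >1..>3
  expect_equal(nrow(rep_oa$summary), 10)  # KW + >1..>9
})

test_that("significance counts use the at-least-n-plus-one rule and are monotone", {
  tbl <- simulate_feature_table(cohort_config(n_participants = 12, seed = 17),
                                shifted_features = c("scl_mean", "temp_delta"),
                                shift_per_class = 2)
  reps <- run_screening(tbl, screening_config(mode = "BA"))
  for (r in reps) {
    counts <- r$summary$count[-1]
    expect_true(all(diff(counts) <= 0))   # non-increasing in n
    expect_true(all(counts <= 43))
    # threshold semantics: a feature with exactly 2 significant pairs counts
    # toward >1 only
    n2 <- sum(vapply(r$features, function(f) f$n_significant_pairs, 0) == 2)
    gt1 <- r$summary$count[r$summary$row == "feature_significance_gt_1"]
    gt2 <- r$summary$count[r$summary$row == "feature_significance_gt_2"]
    expect_equal(gt1 - gt2,
                 n2)
  }
})

test_that("BA pair counts never exceed OA counts for matching thresholds", {
  tbl <- simulate_feature_table(cohort_config(n_participants = 12, tests = "Stroop",
                                              seed = 23),
                                shifted_features = "pnn50", shift_per_class = 1.5)
  ba <- run_screening(tbl, screening_config(mode = "BA"))
  oa <- run_screening(tbl, screening_config(mode = "OA"))
  for (n in 1:3) {
    cb <- ba$summary$count[ba$summary$row == sprintf("feature_significance_gt_%d", n)]
    co <- oa$summary$count[oa$summary$row == sprintf("feature_significance_gt_%d", n)]
    expect_lte(cb, co + 1e-9)
  }
})

test_that("the bullet matrix flags all-pair features and intersects across tests", {
  tbl <- simulate_feature_table(cohort_config(n_participants = 14, seed = 29),
                                shifted_features = c("scl_mean", "scl_sd"),
                                shift_per_class = 2.5)
  reps <- run_screening(tbl, screening_config(mode = "BA"))
  bm <- bullet_matrix(reps)
  expect_equal(dim(bm$matrix), c(43L, 4L))
  expect_true(all(c("scl_mean", "scl_sd") %in% bm$common_features))
  # a feature bulleted in only some tests is excluded from the common list
  partial <- rownames(bm$matrix)[rowSums(bm$matrix) %in% 1:3]
  expect_true(all(!partial %in% bm$common_features))
  # mode and feature-set validation
  oa <- run_screening(split_by_test(tbl)[[1]], screening_config(mode = "OA"))
  expect_error(bullet_matrix(list(oa)), "BA")
})

test_that("screening requires normalized tables and multiple classes", {
  cfg <- cohort_config(n_participants = 6, tests = "Stroop", seed = 3)
  labels <- sample_cohort_labels(cfg)
  feats <- labels[rep(seq_len(nrow(labels)), each = 2), ]
  feats$feature <- rep(c("scl_mean", "pnn50"), nrow(labels))
  feats$value <- rnorm(nrow(feats))
  raw <- assemble_dataset(feats[, c("subject", "test", "phase", "feature", "value")],
                          labels, catalogue = c("scl_mean", "pnn50"))
  expect_error(run_screening(raw, screening_config()), "minmax_normalize")
})
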