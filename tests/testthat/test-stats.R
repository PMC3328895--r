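test_that("Lilliefors statistic matches a direct sorted-loop oracle", {
  x <- c(1, 2, 3, 4, 5)
  # brute-force oracle: walk the sorted sample and take the sup distance
  n <- length(x)
  xs <- sort(x)
  Fh <- stats::pnorm(xs, mean(x), stats::sd(x))
  D_oracle <- 0
  for (i in seq_len(n)) {
    D_oracle <- max(D_oracle, abs(Fh[i] - (i - 1) / n), abs(Fh[i] - i / n))
  }
  res <- lilliefors_test(x, n_mc = 200, seed = 1)
  expect_equal(res$statistic, D_oracle, tolerance = 1e-12)
  expect_error(lilliefors_test(rep(2, 10)), "variance")
  expect_error(lilliefors_test(c(1, 2, 3)), "at least 4")
})

test_that("Lilliefors type-I error is calibrated near alpha", {
  # 1000 seeded N(0,1) replicates; n_mc reduced to 1000 per test to stay
  # inside the run-time budget (p-value validity does not depend on n_mc)
  rejections <- vapply(1:1000, function(s) {
    set.seed(s)
    lilliefors_test(stats::rnorm(30), alpha = 0.05, n_mc = 1000,
                    seed = 10000 + s)$reject
  }, logical(1))
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("one-way ANOVA reproduces its printed reference block", {
  tab <- load_accuracy_fixture("cooccurrence", "gray")
  groups <- lapply(seq_len(nrow(tab)), function(i) accuracy_values(tab)[i, ])
  an <- one_way_anova(groups)
  expect_equal(an$df_between, 4)
  expect_equal(an$df_within, 30)
  expect_lt(abs(an$F - 18.29) / 18.29, 0.005)
  expect_lt(abs(an$ss_between - 1165.72) / 1165.72, 0.005)
})

test_that("ANOVA identities and invariances hold", {
  set.seed(41)
  groups <- lapply(1:4, function(i) rnorm(8, mean = i))
  an <- one_way_anova(groups)
  # SS additivity against the direct grand-mean sum
  allx <- unlist(groups)
  expect_equal(an$ss_total, sum((allx - mean(allx))^2), tolerance = 1e-9)
  expect_equal(an$ss_total, an$ss_between + an$ss_within, tolerance = 1e-9)
  expect_equal(an$df_total, an$df_between + an$df_within)
  # shift invariance and scale invariance of F
  an_shift <- one_way_anova(lapply(groups, `+`, 100))
  expect_equal(an_shift$F, an$F, tolerance = 1e-9)
  an_scale <- one_way_anova(lapply(groups, `*`, 3.7))
  expect_equal(an_scale$F, an$F, tolerance = 1e-9)
  # identical means -> zero between SS
  an0 <- one_way_anova(list(c(1, 2, 3), c(3, 1, 2)))
  expect_equal(an0$ss_between, 0, tolerance = 1e-12)
  expect_equal(an0$F, 0, tolerance = 1e-12)
  expect_error(one_way_anova(list(1:3)), "2 groups")
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "within")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(42)
  for (i in 1:5) {
    g1 <- rnorm(10); g2 <- rnorm(12, mean = 0.5)
    an <- one_way_anova(list(g1, g2))
    t_ <- stats::t.test(g1, g2, var.equal = TRUE)$statistic
    expect_equal(an$F, unname(t_^2), tolerance = 1e-9)
    expect_equal(an$p_value,
                 stats::t.test(g1, g2, var.equal = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Tukey HSD separates extremes and not duplicates", {
  dup <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_false(tukey_hsd(dup)$significant["a", "b"])
  far <- list(lo = rnorm(5, 0, 0.1), hi = rnorm(5, 100, 0.1))
  tk <- tukey_hsd(far)
  expect_true(tk$significant["lo", "hi"])
  expect_equal(tk$best_set, "hi")
  # significance matrix is symmetric with an empty diagonal
  expect_equal(tk$significant, t(tk$significant))
  expect_false(any(diag(tk$significant)))
})

test_that("compare_classifiers reproduces the printed workflow decisions", {
  # Markov Lab with NB pinned out: df 3/36, F 47.11
  tab6 <- load_accuracy_fixture("markov", "lab")
  rep6 <- compare_classifiers(tab6, excluded = "NB")
  expect_equal(rep6$anova$df_between, 3)
  expect_equal(rep6$anova$df_within, 36)
  expect_lt(abs(rep6$anova$F - 47.11) / 47.11, 0.005)
  expect_equal(rep6$best_set, "SVM")

  # Butterworth Lab: ANOVA accepts, Tukey skipped
  tab1 <- load_accuracy_fixture("butterworth", "lab")
  rep1 <- compare_classifiers(tab1, excluded = character(0))
  expect_gt(rep1$anova$p_value, 0.05)
  expect_null(rep1$tukey)
  expect_true(rep1$no_significant_differences)

  # five identical rows: F = 0, no Tukey
  row <- c(60, 61, 62, 63, 64)
  same <- matrix(rep(row, 5), 5, byrow = TRUE,
                 dimnames = list(c("NB", "LMT", "RT", "RF", "SVM"), NULL))
  rep_same <- compare_classifiers(same, excluded = character(0))
  expect_equal(rep_same$anova$F, 0, tolerance = 1e-12)
  expect_null(rep_same$tukey)

  expect_error(compare_classifiers(same, excluded = c("NB", "LMT", "RT", "RF")),
               "fewer than 2")
  expect_error(compare_classifiers(same, excluded = "QDA"), "unknown")
})
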