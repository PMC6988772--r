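test_that("spearman is a rank statistic: monotone-transform invariant, signed", {
  x <- c(2, 5, 1, 9, 4, 7, 3, 8, 6, 10)
  expect_equal(spearman_test(x, x^3)$r_s, 1)
  expect_equal(spearman_test(x, -x)$r_s, -1)
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(15); b <- rnorm(15)
    r1 <- spearman_test(a, b)
    r2 <- spearman_test(exp(a), qlogis(plogis(b)^(1 / 3))) # monotone maps
    expect_equal(r1$r_s, r2$r_s, tolerance = 1e-12)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)
  }
  expect_error(spearman_test(rep(1, 6), 1:6), "constant")
  expect_error(spearman_test(1:3, 1:3), "n >= 4")
})

test_that("exact small-n spearman p matches the reference exact distribution", {
  # tie-free n = 8: cor.test's exact AS89 p is an independent oracle for the
  # full 8!-permutation two-tailed p
  x <- c(1, 3, 2, 5, 4, 7, 8, 6)
  y <- c(2, 1, 4, 3, 6, 8, 5, 7)
  mine <- spearman_test(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(mine$method, "exact")
  expect_equal(mine$r_s, unname(ref$estimate))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("t-approximation p agrees with cor.test for larger n", {
  set.seed(5)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  mine <- spearman_test(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(mine$r_s, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
})

test_that("rout keeps everything at Q = 0 and flags gross contaminants", {
  set.seed(21)
  x <- seq_len(40)
  y <- 2 + 0.5 * x + rnorm(40)
  expect_true(all(rout_outliers(x, y, Q = 0)))
  yc <- y
  yc[c(5, 20, 35)] <- yc[c(5, 20, 35)] + 12   # ~12 sigma
  keep <- rout_outliers(x, yc, Q = 1)
  expect_false(any(keep[c(5, 20, 35)]))
  expect_equal(sum(!keep), 3)
  expect_warning(rout_outliers(1:6, rnorm(6)), "n < 10")
})

test_that("rout mask partitions the sample (n_used + outliers = n)", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(25); y <- x + rnorm(25)
    keep <- rout_outliers(x, y)
    expect_length(keep, 25)
    expect_type(keep, "logical")
  }
})

test_that("correlate_screen reports r_s, p, n_used per pair and flags outliers", {
  set.seed(41)
  n <- 30
  tbl <- data.frame(donor_id = paste0("D", 1:n),
                    a = rnorm(n), c = rnorm(n))
  tbl$b <- -tbl$a + rnorm(n, 0, 0.4)
  tbl$b[7] <- tbl$b[7] + 15
  out <- correlate_screen(tbl, data.frame(x = c("a", "a"), y = c("b", "c")))
  expect_equal(nrow(out), 2)
  expect_lt(out$r_s[1], -0.7)
  expect_equal(out$n_used[1] + out$n_outliers[1], n)
  expect_match(out$outlier_ids[1], "D7")
  expect_error(correlate_screen(tbl, data.frame(x = "a", y = "zz")),
               "not found")
  # no outliers present -> n_used = n_input
  tbl2 <- data.frame(a = seq_len(20), b = seq_len(20) + rnorm(20, 0, 0.1))
  out2 <- correlate_screen(tbl2, data.frame(x = "a", y = "b"))
  expect_equal(out2$n_used, 20)
})

test_that("unpaired t-test: null, separation, and permutation oracle", {
  expect_error(ttest_unpaired(c(1, 1, 1), c(1, 1, 1)), "variance")
  r0 <- ttest_unpaired(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  r1 <- ttest_unpaired(c(1, 2, 3), c(11, 12, 13))
  expect_lt(r1$p, 0.001)
  # moderate-n fixed groups: permutation p of |t| within MC error of Student p
  set.seed(52)
  a <- rnorm(12, 0.9); b <- rnorm(12)
  obs <- ttest_unpaired(a, b)
  pool <- c(a, b)
  perm <- replicate(4000, {
    idx <- sample(24, 12)
    abs(ttest_unpaired(pool[idx], pool[-idx])$t)
  })
  expect_lt(abs(mean(perm >= abs(obs$t)) - obs$p), 0.03)
})

test_that("roc_auc equals brute-force pair counting, with valid CI", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "classes")
  set.seed(61)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    score <- sample(1:6, n, replace = TRUE)   # ties included
    label <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(label) || all(label)) next
    r <- roc_auc(score, label)
    expect_equal(r$auc, brute_auc(score, label), tolerance = 1e-12)
    expect_lte(r$ci_low, r$auc)
    expect_gte(r$ci_high, r$auc)
    expect_gte(r$ci_low, 0)
    expect_lte(r$ci_high, 1)
  }
  # auto orientation folds below-chance AUC and flags the direction
  r <- roc_auc(c(3, 2, 1), c(FALSE, FALSE, TRUE), orientation = "auto")
  expect_gte(r$auc, 0.5)
  expect_equal(r$direction, "positives_lower")
})
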