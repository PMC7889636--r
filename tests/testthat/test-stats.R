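test_that("the Lilliefors screen separates normal from exponential shapes", {
  # plug-in-standardized normal quantiles have a small KS distance
  x <- qnorm((1:20 - 0.5) / 20)
  r <- ks_normality(x, mc = 500, seed = 1)
  expect_lt(r$statistic, 0.1)
  expect_true(r$p_value >= 0 && r$p_value <= 1)

  # a strongly exponential sample scores a larger distance
  y <- qexp((1:50 - 0.5) / 50)
  r2 <- ks_normality(y, mc = 500, seed = 1)
  expect_gt(r2$statistic, r$statistic)
  expect_lt(r2$p_value, 0.05)

  expect_error(ks_normality(c(1, 2)), "at least 3")
  expect_error(ks_normality(rep(1, 5)), "zero variance")
  # deterministic under a fixed calibration seed
  expect_equal(ks_normality(x, mc = 300, seed = 9)$p_value,
               ks_normality(x, mc = 300, seed = 9)$p_value)
})

test_that("two-group t-tests match the textbook pooled formula", {
  mat <- data.frame(group = rep(c("2c", "2d"), c(4, 4)),
                    f = c(1.2, 1.4, 1.1, 1.3, 0.9, 1.0, 0.8, 0.95))
  r <- two_group_ttest(mat, "f", "2c", "2d")
  x <- mat$f[1:4]; y <- mat$f[5:8]
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_exp <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(r$statistic, t_exp, tolerance = 1e-12)
  expect_equal(r$df, 6)
  expect_equal(r$p_value, 2 * pt(-abs(t_exp), 6), tolerance = 1e-12)

  # swapping groups negates t, p unchanged
  r2 <- two_group_ttest(mat, "f", "2d", "2c")
  expect_equal(r2$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-12)

  # identical degenerate samples -> t = 0, p = 1
  mat2 <- data.frame(group = rep(c("2c", "2d"), each = 3), f = rep(2, 6))
  r3 <- two_group_ttest(mat2, "f", "2c", "2d")
  expect_equal(r3$statistic, 0); expect_equal(r3$p_value, 1)

  # scale invariance of t
  mat$f <- mat$f * 1e3
  expect_equal(two_group_ttest(mat, "f", "2c", "2d")$statistic, t_exp,
               tolerance = 1e-9)
})

test_that("summary-statistic t-tests reproduce published-row arithmetic", {
  # the 2c-vs-2d left-ICA lumen comparison from its printed summaries
  r <- ttest_from_summary(0.12, 0.009, 10, 0.09, 0.005, 9)
  s2a <- 0.009^2 * 10; s2b <- 0.005^2 * 9
  sp2 <- (9 * s2a + 8 * s2b) / 17
  t_exp <- 0.03 / sqrt(sp2 * (1 / 10 + 1 / 9))
  expect_equal(r$statistic, t_exp, tolerance = 1e-12)
  expect_equal(r$df, 17)
  expect_lt(r$p_value, 0.05)  # significant, as published

  # Welch variant: hand-checked df
  rw <- ttest_from_summary(0.12, 0.009, 10, 0.09, 0.005, 9, "welch")
  df_exp <- (0.009^2 + 0.005^2)^2 / (0.009^4 / 9 + 0.005^4 / 8)
  expect_equal(rw$df, df_exp, tolerance = 1e-12)
})

test_that("paired asymmetry testing behaves at its degenerate corners", {
  mat <- data.frame(group = "2c", L = c(1, 2, 3, 4), R = c(1, 2, 3, 4))
  r <- paired_asymmetry_test(mat, "L", "R", "2c")
  expect_equal(r$statistic, 0); expect_equal(r$p_value, 1)

  mat$R <- mat$L - 0.5   # constant nonzero offset, zero variance
  expect_error(paired_asymmetry_test(mat, "L", "R", "2c"),
               "degenerate-variance")

  mat$R[1] <- NA
  expect_error(paired_asymmetry_test(mat, "L", "R", "2c"), "pairing error")
})

test_that("the asymmetry test has power in 2d cohorts but not control ones", {
  params <- default_group_params()
  rej <- c(`2c` = 0, `2d` = 0)
  n_seed <- 30
  for (s in seq_len(n_seed)) {
    m <- direct_feature_matrix(
      cohort_config(counts = c(`2c` = 10, `2d` = 9), seed = 1000 + s),
      params, include_velocities = TRUE)
    for (g in c("2c", "2d")) {
      p <- paired_asymmetry_test(m, "vel_CCA_L", "vel_CCA_R", g)$p_value
      rej[g] <- rej[g] + (p <= 0.05)
    }
  }
  expect_gt(rej[["2d"]], n_seed / 2)   # rejects in the majority of seeds
  expect_lt(rej[["2c"]], n_seed / 4)   # near-level behaviour in control
})

test_that("two-way ANOVA matches a from-scratch balanced decomposition", {
  # balanced 2x2, n = 3 per cell
  y <- c(5.1, 4.9, 5.3,   6.2, 6.0, 6.4,
         5.8, 5.6, 6.0,   7.5, 7.3, 7.8)
  pathology <- rep(rep(c("control", "diabetes"), each = 3), 2)
  duration <- rep(c("1", "2"), each = 6)
  tab <- anova_on_scores(y, pathology, duration)

  # textbook sums of squares for the additive model
  gm <- mean(y)
  ssA <- 6 * sum((tapply(y, pathology, mean) - gm)^2)
  ssB <- 6 * sum((tapply(y, duration, mean) - gm)^2)
  fitted <- tapply(y, pathology, mean)[pathology] +
    tapply(y, duration, mean)[duration] - gm
  ssE <- sum((y - fitted)^2)
  dfE <- 12 - 3
  expect_equal(tab$F[tab$effect == "pathology"], (ssA / 1) / (ssE / dfE),
               tolerance = 1e-10)
  expect_equal(tab$F[tab$effect == "duration"], (ssB / 1) / (ssE / dfE),
               tolerance = 1e-10)
  expect_equal(unique(tab$df2), dfE)
  expect_equal(tab$p_value[tab$effect == "pathology"],
               pf((ssA / 1) / (ssE / dfE), 1, dfE, lower.tail = FALSE),
               tolerance = 1e-10)

  # degenerate input: all scores equal -> F = 0 everywhere
  tab0 <- anova_on_scores(rep(1, 12), pathology, duration)
  expect_true(all(tab0$F == 0) && all(tab0$p_value == 1))

  # interaction is reported only on request, flagged as such
  tabi <- anova_on_scores(y, pathology, duration, interaction = TRUE)
  expect_true(any(grepl("pathology:duration", tabi$effect)))
  # an empty pathology x duration cell (indices 1..9 drop the late
  # diabetic cell entirely)
  expect_error(anova_on_scores(y[1:9], pathology[1:9], duration[1:9]),
               "design error")
})

test_that("a late-onset pathology shift is detected on the first score axis", {
  # scores built directly: pathology shifts Y1 only at duration 2
  hits <- 0
  n_seed <- 30
  for (s in seq_len(n_seed)) {
    set.seed(500 + s)
    groups <- rep(c("1c", "1d", "2c", "2d"), c(7, 5, 10, 9))
    pathology <- ifelse(grepl("d$", groups), "diabetes", "control")
    duration <- substr(groups, 1, 1)
    y1 <- rnorm(31) + ifelse(groups == "2d", 2.0, 0)
    tab <- anova_on_scores(cbind(Y1 = y1), pathology, duration)
    hits <- hits + (tab$p_value[tab$effect == "pathology"] <= 0.05)
  }
  expect_gt(hits, n_seed / 2)
})
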