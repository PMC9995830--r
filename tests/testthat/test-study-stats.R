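test_that("arcsine square-root transform maps percentages correctly", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(100), pi / 2)
  expect_equal(arcsine_sqrt(50), pi / 4)
  p <- seq(0, 100, by = 0.5)
  expect_true(all(diff(arcsine_sqrt(p)) > 0))
  expect_error(arcsine_sqrt(101), "outside")
  expect_error(arcsine_sqrt(-1), "outside")
  expect_true(is.na(arcsine_sqrt(NA_real_)))
})

test_that("D'Agostino skewness test matches its reference values", {
  # symmetric sample: zero skewness, p = 1
  sym <- rep(c(-2, -1, 0, 1, 2), 4)
  res <- dagostino_skew_test(sym)
  expect_equal(res$skewness, 0)
  expect_equal(res$z_stat, 0)
  expect_equal(res$p_value, 1)

  # frozen oracle values (scipy.stats.skewtest on the same samples)
  r1 <- dagostino_skew_test((1:20)^2)
  expect_equal(r1$skewness, 0.6077099387037892, tolerance = 1e-12)
  expect_equal(r1$z_stat, 1.3197325725817497, tolerance = 1e-10)
  expect_equal(r1$p_value, 0.18692432083125787, tolerance = 1e-10)

  x2 <- c(2.3, 1.1, 4.5, 3.3, 2.2, 5.1, 0.7, 3.9, 2.8, 1.5, 4.2, 3.0,
          2.6, 1.9, 3.7, 4.8, 0.9, 2.1, 3.4, 2.9, 1.2, 5.6, 3.1, 2.4)
  r2 <- dagostino_skew_test(x2)
  expect_equal(r2$z_stat, 0.5587389072624939, tolerance = 1e-10)
  expect_equal(r2$p_value, 0.5763399220107948, tolerance = 1e-10)

  expect_error(dagostino_skew_test(rnorm(8)), "outside the supported range")
  expect_error(dagostino_skew_test(rep(1, 20)), "constant")
})

test_that("D'Agostino test holds its nominal type-I error at n = 63", {
  set.seed(31)
  rej <- vapply(seq_len(1000), function(i) {
    dagostino_skew_test(rnorm(63))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("solve_f2 reproduces the cohort power analysis and is monotone", {
  expect_equal(round(solve_f2(1, 61, 0.05, 0.95), 2), 0.21)
  # power barely above alpha needs almost no effect
  expect_lt(solve_f2(1, 61, 0.05, 0.0501), 1e-3)
  # larger target power -> larger effect needed; more df -> smaller
  expect_gt(solve_f2(1, 61, 0.05, 0.99), solve_f2(1, 61, 0.05, 0.8))
  expect_lt(solve_f2(1, 200, 0.05, 0.95), solve_f2(1, 61, 0.05, 0.95))
  expect_equal(f2_power(solve_f2(1, 61, 0.05, 0.95), 1, 61), 0.95,
               tolerance = 1e-8)
  expect_error(solve_f2(0, 61), "u and v")
  expect_error(solve_f2(1, 61, 0.5, 0.3), "alpha < power")
})

test_that("solve_f2's effect size yields the target power in simulation", {
  n <- 63
  f2 <- solve_f2(1, n - 2, 0.05, 0.95)
  set.seed(32)
  x <- runif(n, 1.45, 10)
  b1 <- sqrt(f2 * n / sum((x - mean(x))^2))
  reps <- 10000
  Y <- b1 * x + matrix(rnorm(n * reps), n, reps)
  xc <- x - mean(x)
  r <- (crossprod(xc, Y) / sqrt(sum(xc^2))) /
    sqrt(colSums(Y^2) - n * colMeans(Y)^2)
  Fs <- (n - 2) * r^2 / (1 - r^2)
  rejection <- mean(Fs > qf(0.95, 1, n - 2))
  expect_lt(abs(rejection - 0.95), 0.01)
})

test_that("single-predictor fits report the textbook statistics", {
  df <- data.frame(time_played = 1:20, recall = (1:20) * 3)
  fit <- suppressWarnings(
    fit_single_predictor(df, "recall", "time_played", transform = FALSE))
  expect_equal(fit$r2_adj, 1)
  expect_lt(fit$p_raw, 1e-12)
  expect_equal(fit$df, c(1, 18))
  expect_equal(fit$n, 20)

  # F-test p invariant to affine rescaling of the predictor
  df$scaled <- df$time_played * 37 - 12
  set.seed(33)
  df$recall <- runif(20, 10, 90)
  f1 <- fit_single_predictor(df, "recall", "time_played")
  f2 <- fit_single_predictor(df, "recall", "scaled")
  expect_equal(f1$p_raw, f2$p_raw)

  df$const <- 5
  expect_error(fit_single_predictor(df, "recall", "const"), "constant")
  df$recall[3] <- NA
  expect_message(fit3 <- fit_single_predictor(df, "recall", "time_played"),
                 "dropped 1")
  expect_equal(fit3$n, 19)
})

test_that("an unrelated predictor rejects at the nominal 5% rate", {
  set.seed(34)
  rej <- vapply(seq_len(1000), function(i) {
    df <- data.frame(recall = runif(63, 5, 95), x = runif(63))
    fit_single_predictor(df, "recall", "x")$p_raw < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("sequential Bonferroni multiplies by tests so far and caps at 1", {
  expect_equal(bonferroni_sequential(0.03), 0.03)
  expect_equal(bonferroni_sequential(c(0.03, 0.03, 0.03)),
               c(0.03, 0.06, 0.09))
  expect_equal(bonferroni_sequential(c(0.6, 0.9)), c(0.6, 1))
  expect_equal(bonferroni_sequential(c(0.02, 0.02), multiplier = "planned",
                                     n_planned = 4),
               c(0.08, 0.08))
  expect_error(bonferroni_sequential(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("chi-squared independence test matches hand computation", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  res <- chisq_independence(tab)
  # all expected counts are 15: sum((O-E)^2/E) = 4 * 25/15
  expect_equal(res$statistic, 4 * 25 / 15)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(4 * 25 / 15, 1, lower.tail = FALSE))

  set.seed(35)
  nine_by_two <- matrix(rpois(18, 20) + 1, 9, 2)
  expect_equal(chisq_independence(nine_by_two)$df, 8)

  prop <- outer(c(1, 2, 3), c(2, 5)) # proportional rows: exact independence
  res_p <- chisq_independence(prop)
  expect_equal(res_p$statistic, 0)
  expect_equal(res_p$p_value, 1)

  expect_error(chisq_independence(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(chisq_independence(matrix(1:3, 3, 1)), "at least 2 x 2")
})

test_that("group summaries flag groups whose spread dwarfs the mean's CI", {
  const <- group_summary(rep(5, 10), "const")
  expect_equal(const$mean, 5)
  expect_equal(const$ci95_low, const$ci95_high)
  expect_false(const$poor_estimate)

  set.seed(36)
  big <- group_summary(rnorm(400), "normal")
  expect_true(big$poor_estimate)   # quartiles ~ +/-0.67 vs CI ~ +/-0.098

  # brute-force re-evaluation of the flag rule on random samples
  for (i in 1:20) {
    vals <- rnorm(sample(5:40, 1), sd = runif(1, 0.1, 3))
    gs <- group_summary(vals)
    q <- unname(quantile(vals, c(0.25, 0.75), type = 7))
    half <- qt(0.975, length(vals) - 1) * sd(vals) / sqrt(length(vals))
    expected <- (q[1] < mean(vals) - half) || (q[2] > mean(vals) + half)
    expect_identical(gs$poor_estimate, expected)
  }
  expect_error(group_summary(3), "at least 2")
})

test_that("likert summaries row-normalize to percentages", {
  expect_equal(unname(likert_summary(matrix(c(0, 0, 30), 1))[1, ]),
               c(0, 0, 100))
  expect_equal(unname(likert_summary(matrix(c(10, 10, 10), 1))[1, ]),
               rep(100 / 3, 3))
  got <- unname(likert_summary(matrix(c(3, 7, 20), 1))[1, ])
  expect_equal(round(got, 1), c(10, 23.3, 66.7))
  expect_true(all(abs(rowSums(likert_summary(matrix(1:6, 2))) - 100) < 0.1))
  expect_warning(likert_summary(rbind(c(0, 0, 0), c(1, 2, 3))), "empty")
  expect_error(likert_summary(matrix(1:4, 2)), "3 columns")
})

test_that("the pipeline stops at the first feasible model and is consistent", {
  cohort <- generate_cohort(effect_spec(planted_f2 = 0.35, n = 63, seed = 40))
  plan <- list(c("recall", "time_played"),
               c("recall", "farming_experience"),
               c("recall", "sign_head_nod"))
  rep1 <- run_study_pipeline(cohort, plan)
  expect_equal(rep1$stopped_at, 1L)
  expect_equal(rep1$feasible_model, "time_played")
  expect_length(rep1$models, 1)
  expect_equal(rep1$p_corrected,
               bonferroni_sequential(rep1$p_raw))
  expect_equal(rep1$power$f2, solve_f2(1, 61), tolerance = 1e-10)
  expect_s3_class(rep1$skew_tests$recall, "skew_test")

  # categorical predictors get per-level group summaries
  plan2 <- list(c("recall", "farming_experience"),
                c("recall", "time_played"))
  rep2 <- run_study_pipeline(cohort, plan2)
  expect_true("farming_experience" %in% names(rep2$group_summaries))
  expect_setequal(names(rep2$group_summaries$farming_experience),
                  c("TRUE", "FALSE"))

  # a null cohort usually runs the full plan without a feasible model
  null_cohort <- generate_cohort(effect_spec(planted_f2 = 0, n = 63,
                                             seed = 41))
  rep3 <- run_study_pipeline(null_cohort, plan)
  expect_equal(length(rep3$p_raw), ifelse(is.na(rep3$stopped_at), 3,
                                          rep3$stopped_at))
  expect_error(run_study_pipeline(cohort, list()), "plan")
})
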