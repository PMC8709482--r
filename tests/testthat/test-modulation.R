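test_that("control baseline pools pre/post responses after outlier exclusion", {
  expect_equal(control_baseline(rep(1, 10), rep(2, 10)), 1.5)
  expect_equal(control_baseline(rep(0.4, 10), rep(0.4, 10)), 0.4)
  # matches a hand application of the rule on a pool with one extreme value
  pre <- c(0.5, 0.52, 0.48, 0.51, 0.49, 0.5, 0.53, 0.47, 0.5, 0.51)
  post <- c(0.49, 0.5, 0.52, 0.48, 0.51, 0.5, 0.49, 0.52, 0.5, 5.0)
  pool <- c(pre, post)
  keep <- abs(pool - mean(pool)) <= 2.5 * sd(pool)
  expect_equal(control_baseline(pre, post), mean(pool[keep]))
  expect_error(control_baseline(numeric(0), rep(1, 10)), "non-empty")
})

test_that("normalization to control is a plain percentage", {
  expect_equal(normalize_to_control(0.5, 0.5), 100)
  expect_equal(normalize_to_control(1.29, 0.5), 258)
  expect_equal(normalize_to_control(0, 0.5), 0)
  expect_error(normalize_to_control(1, 0), "> 0")
})

test_that("R2 filtering drops floor and contamination cases, keeps the rest", {
  d <- data.frame(
    r1_pp = c(0.015, 0.05, 0.05, 0.020, 0.05),
    r2_pp = c(0.010, 0.06, 0.02, 0.010, 0.05)
  )
  f <- filter_r2(d)
  # r1 below 0.02 floor; r2 > r1; retained; boundary r1 = 0.02 retained
  # (rule is "below"); boundary r2 = r1 retained (rule is strict >)
  expect_equal(f$r2_retained, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(is.na(f$r2_pp), !f$r2_retained)
  expect_equal(f$r1_pp, d$r1_pp) # R1 always kept

  # lowering the floor never removes more doublets
  f_low <- filter_r2(d, floor_mv = 0.01)
  expect_true(all(f$r2_retained <= f_low$r2_retained))

  expect_equal(r2_r1_ratio(f[3, ]), 40)
  expect_equal(r2_r1_ratio(data.frame(r1_pp = 0.5, r2_pp = 0.1,
                                      r2_retained = TRUE)), 20)
  expect_error(r2_r1_ratio(f[1, ]), "removed")
})

test_that("paired comparison routes on Shapiro-Wilk normality", {
  x <- c(1.2, 1.5, 1.1, 1.4, 1.3, 1.6, 1.25, 1.45, 1.35, 1.5, 1.15, 1.4, 1.3)
  expect_equal(compare_to_control(x, x)$p_raw, 1)
  expect_equal(compare_to_control(x, x)$test_used, "degenerate")

  withr::with_seed(21, {
    y <- x + rnorm(13, 0, 0.05)
    r <- compare_to_control(y, x)
    expect_equal(r$test_used, "t_paired")
    expect_equal(r$p_raw, t.test(y, x, paired = TRUE)$p.value)

    # a gross outlier in the differences violates normality -> Wilcoxon
    y2 <- x; y2[1] <- x[1] + 30; y2[-1] <- x[-1] + rnorm(12, 0, 0.01)
    r2 <- compare_to_control(y2, x)
    expect_equal(r2$test_used, "wilcoxon")
    expect_equal(r2$p_raw,
                 suppressWarnings(wilcox.test(y2, x, paired = TRUE)$p.value))
  })
  expect_error(compare_to_control(1:2, 2:3), "at least 3")
})

test_that("the t branch fires at the Shapiro-Wilk nominal rate under normality", {
  withr::with_seed(31, {
    picks <- replicate(500, {
      d <- rnorm(13)
      compare_to_control(d + 5, rep(5, 13))$test_used
    })
  })
  frac_t <- mean(picks == "t_paired")
  expect_gt(frac_t, 0.92) # nominal 0.95, 3 binomial SE ~ 0.03
  expect_lt(frac_t, 0.98)
})

test_that("large shifts are detected with near-certain power", {
  withr::with_seed(41, {
    p <- replicate(200, {
      base <- rnorm(13, 10, 1)
      compare_to_control(base + 3, base + rnorm(13))$p_raw
    })
  })
  expect_gt(mean(p < 0.05), 0.99)
})

test_that("Bonferroni adjustment multiplies and clamps", {
  expect_equal(bonferroni_adjust(0.01, m = 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, m = 5), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.7), m = 1), c(0.2, 0.7))
  expect_equal(bonferroni_adjust(c(0.01, 0.02)), c(0.02, 0.04))
})

test_that("modulation analysis recovers injected effects with correct labels", {
  em <- effect_model(
    modulation = effect_table(cti_ms = c(200, 250), value = c(2, 0.5)),
    amplitude_cv = 0.1
  )
  x <- simulate_experiment(mc_protocol(), em, n_participants = 13, seed = 9)
  mod <- analyze_modulation(x)
  expect_s3_class(mod, "semp_modulation")
  expect_equal(nrow(mod), 5)

  r200 <- mod[mod$cti_ms == 200, ]
  r250 <- mod[mod$cti_ms == 250, ]
  expect_equal(r200$normalized_pct, 200, tolerance = 0.1)
  expect_equal(r250$normalized_pct, 50, tolerance = 0.1)
  expect_equal(r200$direction, "facilitation")
  expect_equal(r250$direction, "inhibition")
  expect_true(all(mod$p_adjusted >= mod$p_raw))
  expect_true(all(mod$direction[mod$cti_ms < 200] == "none"))
})

test_that("normalized percentages and p-values are scale equivariant", {
  x <- simulate_experiment(mc_protocol(), effect_model(modulation = 1.5),
                           n_participants = 10, seed = 14)
  m1 <- analyze_modulation(x)
  x2 <- x
  x2$r1_pp <- x2$r1_pp * 3.7
  x2$r2_pp <- x2$r2_pp * 3.7
  m2 <- analyze_modulation(x2)
  expect_equal(m2$normalized_pct, m1$normalized_pct)
  expect_equal(m2$p_raw, m1$p_raw)
  expect_equal(m2$test_used, m1$test_used)
})
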