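# Doubling times, growth regression, slope comparison, ANOVA, paired t.

test_that("interval doubling time handles growth, shrinkage and errors", {
  expect_equal(interval_doubling_time(0, 24, 100, 200), 24)
  expect_equal(interval_doubling_time(4, 96, 30000, 240000), 92 / 3)  # 3 doublings
  expect_equal(interval_doubling_time(0, 24, 200, 100), -24)
  expect_error(interval_doubling_time(24, 0, 100, 200), "t1")
  expect_error(interval_doubling_time(0, 24, 100, 100), "degenerate")
  expect_error(interval_doubling_time(0, 24, -5, 100), "> 0")
})

test_that("interval doubling time is invariant to count scaling and time shifts", {
  withr::with_seed(10, {
    for (i in 1:20) {
      t0 <- runif(1, 0, 50); dt <- runif(1, 5, 60)
      n0 <- runif(1, 10, 1e5); n1 <- n0 * 2^(runif(1, 0.1, 3))
      base <- interval_doubling_time(t0, t0 + dt, n0, n1)
      expect_equal(interval_doubling_time(t0 + 10, t0 + dt + 10, n0, n1), base)
      expect_equal(interval_doubling_time(t0, t0 + dt, 7 * n0, 7 * n1), base)
    }
  })
})

test_that("mean doubling time recovers the generating value exactly", {
  for (dt in c(10, 26, 33, 55, 100)) {
    s <- simulate_growth_counts(19.66, dt, c(4, 24, 48, 72, 96))
    expect_equal(mean_doubling_time(s), dt, tolerance = 1e-9)
  }
  s <- growth_series(c(0, 24, 48), c(100, 200, 400))
  expect_equal(mean_doubling_time(s), 24)
  s2 <- growth_series(c(10, 34, 58), c(100, 200, 400))  # translated times
  expect_equal(mean_doubling_time(s2), 24)
  expect_warning(dtv <- mean_doubling_time(
    growth_series(c(0, 24, 48), c(100, 100, 200))), "degenerate")
  expect_equal(dtv, 24)
  expect_error(mean_doubling_time(growth_series(c(0, 24), c(50, 50))),
               "degenerate|constant")
})

test_that("growth regression is exact on linear data and matches closed form", {
  t <- c(4, 24, 48, 72, 96)
  s <- growth_series(t, 0.39 * t + 12)
  r <- suppressWarnings(fit_growth_regression(s))
  expect_equal(r$slope, 0.39, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  # closed-form OLS oracle on noisy data
  withr::with_seed(2, {
    y <- 5 + 0.3 * t + rnorm(5)
    r2 <- fit_growth_regression(growth_series(t, y))
    expect_equal(r2$slope, cov(t, y) / var(t), tolerance = 1e-12)
    expect_equal(r2$intercept, mean(y) - r2$slope * mean(t), tolerance = 1e-12)
  })
  # constant response: slope 0, r^2 defined as 0
  rc <- suppressWarnings(fit_growth_regression(growth_series(t, rep(50, 5))))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)
  expect_error(fit_growth_regression(growth_series(c(0, 1), c(1, 2))),
               "3 points")
  # log-linear option recovers doublings per hour
  sl <- suppressWarnings(
    fit_growth_regression(simulate_growth_counts(100, 25, t),
                          response = "log2_count"))
  expect_equal(sl$slope, 1 / 25, tolerance = 1e-9)
})

test_that("slope-equality test separates and degenerates correctly", {
  t <- c(4, 24, 48, 72, 96)
  withr::with_seed(5, {
    y <- 10 + 0.4 * t + rnorm(5, 0, 2)
    d <- data.frame(t = t, y = y)
    same <- slopes_equal_test(d, d)
    expect_lt(same$f_statistic, 1e-6)
    expect_equal(same$p_value, 1, tolerance = 1e-6)
  })
  a <- data.frame(t = t, y = 0.39 * t + 3)   # noiseless, different slopes
  b <- data.frame(t = t, y = 0.30 * t + 3)
  sep <- slopes_equal_test(a, b)
  expect_lt(sep$p_value, 1e-12)
  expect_error(slopes_equal_test(data.frame(t = c(1, 1, 1), y = 1:3),
                                 data.frame(t = c(1, 1, 1), y = 2:4)),
               "degenerate")
  # accepts growth_series input
  s1 <- simulate_growth_counts(100, 30, t, "poisson", seed = 8)
  s2 <- simulate_growth_counts(100, 30, t, "poisson", seed = 9)
  st <- slopes_equal_test(s1, s2)
  expect_true(st$p_value >= 0 && st$p_value <= 1)
})

test_that("one-way ANOVA matches a sums-of-squares oracle and identities", {
  g <- list(c(1, 2, 3), c(2, 3, 4))
  res <- one_way_anova(g)
  # brute-force decomposition computed independently
  all_v <- unlist(g)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - mean(all_v))^2,
                    numeric(1)))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  f_oracle <- (ssb / 1) / (ssw / 4)
  expect_equal(res$f_statistic, f_oracle, tolerance = 1e-12)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  # two identical groups: F = 0, p = 1
  same <- one_way_anova(list(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)
  # k = 2: F equals the squared pooled-variance t statistic
  withr::with_seed(6, {
    x <- rnorm(8); y <- rnorm(10, 0.5)
    f2 <- one_way_anova(list(x, y))$f_statistic
    tt <- t.test(x, y, var.equal = TRUE)$statistic
    expect_equal(f2, unname(tt)^2, tolerance = 1e-10)
  })
  # translation invariance
  shifted <- one_way_anova(lapply(g, `+`, 100))
  expect_equal(shifted$f_statistic, res$f_statistic, tolerance = 1e-9)
  # zero within-group variance with distinct means: explicit Inf / 0
  degen <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(degen$f_statistic, Inf)
  expect_equal(degen$p_value, 0)
  expect_error(one_way_anova(list(1:3)), "2")
  expect_error(one_way_anova(list(1, 1:3)), "2 values")
})

test_that("paired t-test matches the difference oracle and is symmetric", {
  x <- c(1, 2, 3, 4)
  expect_equal(paired_t_test(x, x), list(t = 0, df = 3L, p_value = 1))
  withr::with_seed(7, {
    x <- rnorm(12); y <- rnorm(12, 0.3)
    res <- paired_t_test(x, y)
    d <- x - y
    t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
    expect_equal(res$t, t_oracle, tolerance = 1e-12)
    expect_equal(res$p_value, 2 * pt(abs(t_oracle), 11, lower.tail = FALSE),
                 tolerance = 1e-12)
    swapped <- paired_t_test(y, x)
    expect_equal(swapped$t, -res$t)
    expect_equal(swapped$p_value, res$p_value)
  })
  # constant non-zero difference: no sampling variance
  cz <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(cz$t, Inf)
  expect_equal(cz$p_value, 0)
})
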