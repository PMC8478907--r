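# Initial-rate and biphasic fits, fold ratios, and threshold detection.

test_that("initial-rate fits are exact on noiseless linear decays", {
  t <- c(0, 60, 120, 180, 240)
  tc <- time_course(t, 1 - 2.40e-5 * t)
  fit <- fit_initial_rate(tc)
  expect_equal(fit$k, 2.40e-5, tolerance = 1e-12)
  expect_identical(fit$n_used, 5L)

  flat <- fit_initial_rate(time_course(t, rep(1, 5)))
  expect_identical(flat$k, 0)

  rising <- fit_initial_rate(time_course(t, c(0.9, 0.92, 0.94, 0.96, 0.98)))
  expect_identical(rising$k, 0)
  expect_true(rising$flagged)

  expect_error(time_course(c(0, 60, 60), c(1, 0.9, 0.8)), "increasing")
  expect_error(time_course(c(0, 60), c(1, 0.9)), "insufficient")
})

test_that("the initial window follows the uncut-fraction prefix rule", {
  # fast decay: only the first points are in the linear regime
  t <- seq(0, 200, by = 25)
  f <- pmax(0, 1 - 1.68e-2 * t)          # hits 0.5 near t = 30
  fit <- fit_initial_rate(time_course(t, f))
  expect_identical(fit$n_used, 3L)       # prefix >= 0.5 is short, floor of 3
  expect_lte(fit$window[2], 50)
  # explicit window override
  fit2 <- fit_initial_rate(time_course(t, f), window = c(0, 50))
  expect_identical(fit2$n_used, 3L)
})

test_that("noisy initial-rate estimates are accurate and nearly unbiased", {
  k_true <- 1.68e-2
  t <- seq(0, 28, by = 4)  # 8 points within the linear regime
  ks <- vapply(1:100, function(s) {
    tc <- gen_timecourse(k_true, t, fraction_sd = 0.02, seed = 4000 + s)
    fit_initial_rate(tc)$k
  }, numeric(1))
  expect_gte(sum(abs(ks - k_true) / k_true <= 0.10), 95)
  expect_lt(abs(mean(ks) - k_true) / k_true, 0.02)
})

test_that("biphasic fits recover both segment slopes", {
  t <- c(0, 30, 60, 90, 120, 300, 600, 900, 1200)
  f <- ifelse(t <= 120, 1 - 4.31e-3 * t,
              (1 - 4.31e-3 * 120) - 4.07e-4 * (t - 120))
  fit <- fit_biphasic(time_course(t, f))
  expect_equal(fit$k_fast, 4.31e-3, tolerance = 0.01)
  expect_equal(fit$k_slow, 4.07e-4, tolerance = 0.01)
  expect_identical(fit$t_break, 120)
  expect_gte(fit$k_fast, fit$k_slow)

  # single-slope data: both segments agree and match the single-line SSE
  f1 <- 1 - 2e-4 * t
  d <- fit_biphasic(time_course(t, f1))
  expect_equal(d$k_fast, d$k_slow, tolerance = 1e-6)
  expect_equal(d$sse, d$sse_single, tolerance = 1e-9)

  expect_error(fit_biphasic(time_course(t[1:4], f[1:4])), "insufficient")
})

test_that("fold ratios reproduce reported rate comparisons", {
  expect_identical(report_fold(fold_ratio(4.31e-3, 2.40e-5)), 180)
  expect_equal(fold_ratio(1.68e-2, 2.27e-4), 74.0, tolerance = 5e-3)
  expect_identical(round(fold_ratio(1.41e-4, 2.40e-5)), 6)
  expect_identical(round(fold_ratio(6.23e-5, 2.40e-5)), 3)
  expect_identical(fold_ratio(1.5, 1.5), 1)
  expect_equal(fold_ratio(3, 7) * fold_ratio(7, 3), 1, tolerance = 1e-12)
  expect_error(fold_ratio(1, 0), "positive")
})

test_that("threshold detection brackets the step without interpolating", {
  grid <- -c(0.011, 0.024, 0.033, 0.042, 0.056, 0.064)
  prof <- rate_profile(grid, ifelse(abs(grid) <= 0.042, 1e-4, 1e-2))
  thr <- detect_threshold(prof)
  expect_equal(thr$sigma_low, -0.042)
  expect_equal(thr$sigma_high, -0.056)
  expect_equal(thr$fold_change, 100)

  # invariance under uniform rescaling of the rates
  prof10 <- rate_profile(prof$sigma, 10 * prof$k)
  thr10 <- detect_threshold(prof10)
  expect_equal(c(thr10$sigma_low, thr10$sigma_high, thr10$fold_change),
               c(thr$sigma_low, thr$sigma_high, thr$fold_change))

  expect_null(detect_threshold(rate_profile(grid, rep(1e-3, 6))))
  expect_null(detect_threshold(rate_profile(grid, 1e-4 * 1.2^(1:6))))
  expect_error(detect_threshold(rate_profile(c(-0.01, -0.02, 0.05),
                                             c(1, 2, 3))), "insufficient")
  # a rate of zero below the onset still yields a finite detectable fold
  onset <- rate_profile(grid, c(0, 0, 0, 0, 1e-2, 1e-2))
  expect_equal(detect_threshold(onset)$sigma_low, -0.042)
})

test_that("rates convert consistently between time units", {
  t_s <- c(0, 60, 120, 180, 240, 300)
  f <- 1 - 8e-4 * t_s
  k_s <- fit_initial_rate(time_course(t_s, f))$k
  k_min <- fit_initial_rate(time_course(t_s / 60, f))$k
  expect_equal(k_s, k_min / 60, tolerance = 1e-12)
})
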