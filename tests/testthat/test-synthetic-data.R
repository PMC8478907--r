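# Forward generators: determinism, range guarantees, and round-trip
# exactness against the matching estimators.

test_that("every generator is a pure function of parameters and seed", {
  expect_identical(gen_mobility_table(noise_sd = 0.05, seed = 7),
                   gen_mobility_table(noise_sd = 0.05, seed = 7))
  rmap <- std_map()
  sites <- data.frame(position = c(143, 203), weight = c(2, 1))
  expect_identical(gen_fragment_observations(sites, rmap, 5, seed = 7),
                   gen_fragment_observations(sites, rmap, 5, seed = 7))
  t <- seq(0, 600, by = 60)
  expect_identical(gen_timecourse(1e-3, t, seed = 7),
                   gen_timecourse(1e-3, t, seed = 7))
  expect_identical(
    gen_rate_sigma_profile(-(1:6) / 50, 1e-4, 1e-2, -0.05, rel_noise = 0.2,
                           seed = 7),
    gen_rate_sigma_profile(-(1:6) / 50, 1e-4, 1e-2, -0.05, rel_noise = 0.2,
                           seed = 7))
  # different seeds perturb the noisy outputs
  expect_false(identical(gen_mobility_table(noise_sd = 0.05, seed = 7),
                         gen_mobility_table(noise_sd = 0.05, seed = 8)))
  # and the caller's RNG stream is left untouched
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(gen_mobility_table(noise_sd = 1, seed = 9))
  expect_identical(stats::runif(1), before)
})

test_that("noiseless mobility tables round-trip through the V fit", {
  rec <- gen_mobility_table(h_true = 10.48, noise_sd = 0, seed = 1)
  for (df in split(rec, rec$construct_id)) {
    fit <- vfit_lk0(df[, c("lk", "mobility")])
    expect_equal(fit$lk0_hat, df$size_bp[1] / 10.48, tolerance = 1e-9)
  }
  pooled <- calibrate_helical_repeat(rec)
  expect_equal(pooled$h_mean, 10.48, tolerance = 1e-9)
})

test_that("noiseless fragment observations match circle arithmetic and invert", {
  rmap <- std_map()
  obs <- gen_fragment_observations(data.frame(position = 143, weight = 1),
                                   rmap, length_sd = 0, seed = 1)
  # two fragments per reference cut, each pair summing to N
  expect_identical(nrow(obs), 2L * nrow(rmap$entries))
  for (e in rmap$entries$enzyme) {
    lens <- obs$length_bp[obs$reference_enzyme == e]
    r <- rmap$entries$position[rmap$entries$enzyme == e]
    expect_setequal(lens, fragment_lengths(c(r, 143), 336))
  }
  est <- triangulate_sites(obs, rmap)
  expect_equal(est$position[1], 143)
  expect_equal(est$error_bp[1], 0)
})

test_that("generated observations respect range guarantees", {
  rmap <- std_map()
  obs <- gen_fragment_observations(data.frame(position = 10, weight = 1),
                                   rmap, length_sd = 80, seed = 2)
  expect_true(all(obs$length_bp > 0 & obs$length_bp < 336))
  tc <- gen_timecourse(5e-3, seq(0, 1200, by = 60), fraction_sd = 0.5,
                       seed = 2)
  expect_true(all(tc$uncut_fraction >= 0 & tc$uncut_fraction <= 1))
})

test_that("gap-mixture time courses are multiphasic and fit to two slopes", {
  mix <- data.frame(weight = c(0.5, 0.5), rate = c(4.31e-3, 4.07e-4))
  t <- c(0, 30, 60, 90, 120, 180, 232, 300, 600, 1200, 1800, 2400)
  tc <- gen_timecourse(mix, t, fraction_sd = 0, seed = 1)
  fit <- fit_biphasic(tc)
  # segment slopes of the mixture: mean rate early, w_slow * k_slow late
  expect_equal(fit$k_fast, mean(mix$rate), tolerance = 0.05)
  expect_equal(fit$k_slow, 0.5 * 4.07e-4, tolerance = 0.05)
  # single-rate mode round-trips exactly
  tc1 <- gen_timecourse(4.31e-3, seq(0, 200, by = 25), fraction_sd = 0,
                        seed = 1)
  expect_equal(fit_initial_rate(tc1)$k, 4.31e-3, tolerance = 1e-12)
  expect_error(gen_timecourse(data.frame(weight = c(0.5, 0.4),
                                         rate = c(1e-3, 1e-4)),
                              t, seed = 1), "sum to 1")
})

test_that("synthetic rate profiles carry a detectable threshold", {
  grid <- -c(0.011, 0.024, 0.033, 0.042, 0.056, 0.064)
  prof <- gen_rate_sigma_profile(grid, k_floor = 1e-4, k_plateau = 1e-2,
                                 sigma_threshold = -0.05, rel_noise = 0,
                                 seed = 1)
  thr <- detect_threshold(prof)
  expect_equal(c(thr$sigma_low, thr$sigma_high), c(-0.042, -0.056))
  flat <- gen_rate_sigma_profile(grid, k_floor = 1e-3, k_plateau = 1e-3,
                                 sigma_threshold = -0.05, seed = 1)
  expect_null(detect_threshold(flat))
})
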