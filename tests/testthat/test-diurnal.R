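test_that("diurnal profile preserves the day/night order relation", {
  cfg <- std_config(n_days = 10, noise_cv = 0, transition_width = 0)
  # mean detrending: the day level sits above 1, the night level below
  det <- detrend_daily(generate_diurnal_series(cfg), statistic = "mean")
  prof <- diurnal_profile(det)
  clock_h <- prof$bin_centers / 3600
  night <- clock_h < 6
  expect_true(all(prof$stat_per_bin[night] < 1))
  expect_true(all(prof$stat_per_bin[!night] > 1))
  expect_identical(sum(prof$count_per_bin), length(det))

  # constant series detrends to all-1 bins
  const <- detrend_daily(make_series(rep(7, 2 * 144)))
  expect_true(all(diurnal_profile(const)$stat_per_bin == 1))
  expect_error(diurnal_profile(const, bin_width = 1700), "divide 24 h")
})

test_that("binned profile of a sinusoid matches the closed-form bin average", {
  # smooth 24-h cosine, no noise: day=night level so only the cosine varies
  cfg <- diurnal_sim_config(n_days = 4, day_level = 3, night_level = 3,
                            circadian_amp = 0.3, noise_cv = 0, seed = 1)
  s <- generate_diurnal_series(cfg)
  prof <- diurnal_profile(s, statistic = "mean")
  # closed form: each bin holds samples at offsets 0, 10, 20 min past the
  # bin start; the mean of the cosine over those three points is the
  # cosine at their midpoint (center - 300 s) times (1 + 2 cos(600 w))/3
  w <- 2 * pi / 86400
  mid <- prof$bin_centers - 300
  shrink <- (1 + 2 * cos(600 * w)) / 3
  oracle <- 3 * (1 + 0.3 * cos(w * (mid - 15 * 3600)) * shrink)
  expect_equal(prof$stat_per_bin, oracle, tolerance = 1e-10)
})

test_that("two-stage (per-day first) profile weights days equally", {
  # day 1 contributes one sample to the first bin, day 2 three samples:
  # pooled mean weights by sample, two-stage weights by day
  t0 <- as.POSIXct("2021-06-01", tz = "UTC")
  ts <- c(t0, t0 + 12 * 3600,
          t0 + 86400 + c(0, 600, 1200), t0 + 86400 + 12 * 3600)
  s <- band_power_series(ts, c(0, 1, 3, 3, 3, 1), check_nonneg = FALSE)
  p1 <- diurnal_profile(s, statistic = "mean", per_day_first = TRUE)
  p2 <- diurnal_profile(s, statistic = "mean", per_day_first = FALSE)
  expect_length(p1$stat_per_bin, 48L)
  expect_equal(p1$stat_per_bin[1], mean(c(0, 3)))       # (0 + 3)/2
  expect_equal(p2$stat_per_bin[1], mean(c(0, 3, 3, 3))) # 9/4
  expect_identical(p1$count_per_bin[1], 4L)
})

test_that("time-of-day fit anchors at bin centers and interpolates linearly", {
  bins <- seq(2, 4, length.out = 48)
  s <- make_bin_center_series(bins)
  fit <- fit_time_of_day(s)
  # anchor: fit at a bin center is that bin's mean (machine precision)
  expect_equal(predict_time_of_day(fit, fit$bin_centers), bins)
  # midpoint between bins with means 2 and 4
  fit$bin_means[1:2] <- c(2, 4)
  expect_equal(predict_time_of_day(fit, 1800), 3)
})

test_that("fit wraps across midnight with hand-computed weights", {
  bins <- rep(1, 48); bins[1] <- 5; bins[48] <- 3
  s <- make_bin_center_series(bins)
  fit <- fit_time_of_day(s)
  # 23:52 = 85920 s lies between the last center (23:45) and first (00:15,
  # next day); 7 min of the 30-min span -> a + (7/30) (b - a)
  a <- 3; b <- 5
  expect_equal(predict_time_of_day(fit, 85920), a + (7 / 30) * (b - a))
  # non-wrapping mode clamps instead
  fit_nw <- fit_time_of_day(s, wrap = FALSE)
  expect_equal(predict_time_of_day(fit_nw, 85920), a)
})

test_that("empty bins are interpolated across; single-bin data errors", {
  bins <- seq(1, 3, length.out = 48)
  s <- make_bin_center_series(bins)
  # drop all samples in bins 10-12 (0-based bins 9-11)
  bin_of <- as.numeric(format(s$timestamps, "%H")) * 2 +
    as.numeric(format(s$timestamps, "%M")) %/% 30
  keep <- !(bin_of %in% 9:11)
  s2 <- band_power_series(s$timestamps[keep], s$values[keep],
                          sample_interval = 1800, check_nonneg = FALSE)
  fit <- fit_time_of_day(s2)
  expect_true(all(is.na(fit$bin_means[10:12])))
  # bin values are linear in clock time, so interpolating across the gap
  # recovers the deleted bins exactly
  expect_equal(predict_time_of_day(fit, fit$bin_centers[10:12]),
               bins[10:12])
  one_bin <- make_series(rep(2, 3), interval = 60)
  expect_error(fit_time_of_day(one_bin), "single clock-time bin")
})

test_that("VE is exactly 1 for a pure function of clock time", {
  bins <- 2 + sin(2 * pi * (1:48) / 48)
  s <- make_bin_center_series(bins, n_days = 5)
  ve <- variance_explained(s)
  expect_equal(ve$ve, 1, tolerance = 1e-12)
  expect_equal(ve$var_residual, 0, tolerance = 1e-12)
  expect_error(variance_explained(make_series(rep(2, 288))),
               "zero total variance")
})

test_that("an unrelated fit explains none of a noise series", {
  ves <- vapply(1:20, function(k) {
    flat <- diurnal_sim_config(n_days = 30, day_level = 3, night_level = 3,
                               noise_cv = 0.3, seed = 6000 + k)
    noise <- generate_diurnal_series(flat)
    other <- generate_diurnal_series(
      diurnal_sim_config(n_days = 30, day_level = 3, night_level = 3,
                         noise_cv = 0.3, seed = 7000 + k))
    fit <- fit_time_of_day(other)
    variance_explained(noise, fit = fit)$ve
  }, numeric(1))
  expect_lt(abs(mean(ves)), 0.05)
})

test_that("VE recovers the generator's diurnal variance fraction", {
  cfg <- std_config()
  cfg$noise_cv <- noise_cv_for_fraction(cfg, 0.4)
  ves <- vapply(1:20, function(k) {
    cfg$seed <- 8000 + k
    variance_explained(generate_diurnal_series(cfg))$ve
  }, numeric(1))
  expect_lt(abs(mean(ves) - 0.4), 0.05)
})

test_that("shuffle test: strong diurnal structure attains the p floor", {
  cfg <- std_config(seed = 42)
  cfg$noise_cv <- noise_cv_for_fraction(cfg, 0.4)
  s <- generate_diurnal_series(cfg)
  res <- temporal_shuffle_test(s, n_shuffles = 1000, seed = 11)
  expect_length(res$null_ve, 1000L)
  expect_equal(res$p_value, 1 / 1001)
  expect_lt(res$p_value, 0.001)
  expect_true(all(res$null_ve <= 1))
  expect_lte(res$observed_ve, 1)
  # determinism
  res2 <- temporal_shuffle_test(s, n_shuffles = 1000, seed = 11)
  expect_identical(res2$null_ve, res$null_ve)
  expect_error(temporal_shuffle_test(make_series(rep(1, 10))), "2 days")
})

test_that("VE is monotone in the generator's diurnal fraction", {
  mean_ve <- function(f) {
    cfg <- std_config()
    cfg$noise_cv <- noise_cv_for_fraction(cfg, f)
    mean(vapply(1:20, function(k) {
      cfg$seed <- 9000 + k
      variance_explained(generate_diurnal_series(cfg))$ve
    }, numeric(1)))
  }
  ves <- vapply(c(0.1, 0.25, 0.5), mean_ve, numeric(1))
  expect_true(all(diff(ves) > 0))
})

test_that("windowed VE vanishes for flat-within-window day/night steps", {
  ves_day <- numeric(20); ves_night <- numeric(20); ves_full <- numeric(20)
  for (k in 1:20) {
    cfg <- std_config(noise_cv = 0.2, transition_width = 0,
                      seed = 10000 + k)
    s <- generate_diurnal_series(cfg)
    ves_full[k] <- variance_explained(s)$ve
    ves_day[k] <- windowed_variance_explained(s, c("08:00", "20:00"))$ve
    ves_night[k] <- windowed_variance_explained(s, c("00:00", "06:00"))$ve
  }
  expect_lt(abs(mean(ves_day)), 0.05)
  expect_lt(abs(mean(ves_night)), 0.05)
  expect_gt(mean(ves_full), 0.3)
})

test_that("a within-day ramp restores daytime-window VE", {
  cfg <- std_config(noise_cv = 0.15, circadian_amp = 0.3, seed = 4)
  s <- generate_diurnal_series(cfg)
  expect_gt(windowed_variance_explained(s, c("08:00", "20:00"))$ve, 0.1)
})

test_that("the full-day window reproduces variance_explained exactly", {
  cfg <- std_config(noise_cv = 0.3, seed = 13)
  s <- generate_diurnal_series(cfg)
  expect_equal(windowed_variance_explained(s, c("00:00", "00:00"))$ve,
               variance_explained(s)$ve)
})

test_that("day matrix flags missing cells and keeps row medians at 1", {
  cfg <- std_config(n_days = 3, noise_cv = 0.2, seed = 5)
  det <- detrend_daily(generate_diurnal_series(cfg))
  dm <- day_matrix(det)
  expect_identical(dim(dm$matrix), c(3L, 48L))
  # medians of per-bin medians track (approximately) the daily median of 1
  expect_equal(unname(apply(dm$matrix, 1, median)), rep(1, 3),
               tolerance = 0.06)

  # delete an afternoon and check the cells go missing
  keep <- !(format(det$timestamps, "%Y-%m-%d") == "2021-06-02" &
              format(det$timestamps, "%H") %in% c("13", "14"))
  s2 <- band_power_series(det$timestamps[keep], det$values[keep],
                          check_nonneg = FALSE)
  dm2 <- day_matrix(s2)
  expect_true(all(is.na(dm2$matrix["2021-06-02", 27:30])))
  expect_false(anyNA(dm2$matrix["2021-06-01", ]))

  const <- detrend_daily(make_series(rep(3, 2 * 144)))
  expect_true(all(day_matrix(const)$matrix == 1))
})
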