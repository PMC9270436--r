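test_that("noise-free step takes exactly the two configured levels", {
  cfg <- std_config(n_days = 4, noise_cv = 0, transition_width = 0)
  s <- generate_diurnal_series(cfg)
  expect_length(s, 4 * 144)
  expect_setequal(unique(s$values), c(2, 4))
  clock <- as.numeric(format(s$timestamps, "%H")) * 3600 +
    as.numeric(format(s$timestamps, "%M")) * 60
  expect_true(all(s$values[clock < 6 * 3600] == 2))
  expect_true(all(s$values[clock >= 6 * 3600] == 4))
})

test_that("generation is deterministic given the seed", {
  cfg <- std_config(noise_cv = 0.3, outlier_rate = 0.01, seed = 99)
  s1 <- generate_diurnal_series(cfg)
  s2 <- generate_diurnal_series(cfg)
  expect_identical(s1$values, s2$values)
  s3 <- generate_diurnal_series(std_config(noise_cv = 0.3,
                                           outlier_rate = 0.01,
                                           seed = 100))
  expect_false(identical(s1$values, s3$values))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(generate_diurnal_series(std_config(seed = 5)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("sleep-window mean recovers night_level (Monte-Carlo oracle)", {
  base <- function(seed) std_config(noise_cv = 0.2, transition_width = 0,
                                    seed = seed)
  window_mean <- function(s) {
    clock <- as.numeric(format(s$timestamps, "%H")) * 3600 +
      as.numeric(format(s$timestamps, "%M")) * 60
    mean(s$values[clock < 6 * 3600])
  }
  mc <- vapply(1:50, function(k) {
    window_mean(generate_diurnal_series(base(1000 + k)))
  }, numeric(1))
  se <- sd(mc)
  obs <- window_mean(generate_diurnal_series(base(1)))
  expect_lt(abs(obs - 2), 3 * se)
  expect_lt(abs(mean(mc) - 2), 3 * se / sqrt(50))
})

test_that("invalid generator configs name the offending field", {
  expect_error(diurnal_sim_config(n_days = 0), "n_days")
  expect_error(diurnal_sim_config(n_days = 2, day_level = -1), "day_level")
  expect_error(diurnal_sim_config(n_days = 2, noise_cv = -0.1), "noise_cv")
  expect_error(diurnal_sim_config(n_days = 2, outlier_rate = 1),
               "outlier_rate")
  expect_error(diurnal_sim_config(n_days = 2,
                                  sleep_window = c("00:00", "18:00")),
               "sleep_window")
})

test_that("outlier spikes appear at the configured magnitude and rate", {
  cfg <- std_config(noise_cv = 0.1, outlier_rate = 0.01,
                    outlier_scale = 20, seed = 3)
  s <- generate_diurnal_series(cfg)
  truth <- attr(s, "truth")
  expect_true(all(s$values[truth$outlier_indices] == 20 * 4))
  n <- length(s)
  expect_lt(abs(length(truth$outlier_indices) / n - 0.01),
            3 * sqrt(0.01 * 0.99 / n))
})

test_that("closed-form diurnal fraction matches a direct variance check", {
  cfg <- std_config(noise_cv = 0.25)
  f <- diurnal_variance_fraction(cfg)
  # direct computation from the definition on the noise-free profile
  p <- attr(generate_diurnal_series(std_config(noise_cv = 0)), "truth")$noise_free
  p <- p[1:144]
  var_p <- mean(p^2) - mean(p)^2
  expect_equal(f, var_p / (var_p + mean(p^2) * 0.25^2))
  # inversion round-trip
  cfg$noise_cv <- noise_cv_for_fraction(cfg, 0.4)
  expect_equal(diurnal_variance_fraction(cfg), 0.4)
})

test_that("dual-band pair shares a timestamp grid and mismatches error", {
  ca <- std_config(n_days = 5, seed = 1)
  cb <- std_config(n_days = 5, seed = 2)
  pair <- generate_dual_band_series(dual_band_sim_config(ca, cb, seed = 9))
  expect_identical(as.numeric(pair$a$timestamps),
                   as.numeric(pair$b$timestamps))
  cb_bad <- std_config(n_days = 6)
  expect_error(dual_band_sim_config(ca, cb_bad), "n_days")
})

test_that("artifact_weight = 0 gives uncorrelated detrended bands", {
  flat <- function(seed) {
    diurnal_sim_config(n_days = 30, day_level = 3, night_level = 3,
                       noise_cv = 0.3, seed = seed)
  }
  rs <- vapply(1:20, function(k) {
    pair <- generate_dual_band_series(
      dual_band_sim_config(flat(k), flat(k + 500), artifact_weight = 0,
                           seed = 2000 + k))
    pearson_detrended(pair$a, pair$b)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("artifact_weight = 1 with no band noise gives r = 1", {
  ca <- std_config(n_days = 5, noise_cv = 0, seed = 1)
  cb <- std_config(n_days = 5, noise_cv = 0, seed = 2)
  pair <- generate_dual_band_series(
    dual_band_sim_config(ca, cb, artifact_weight = 1, seed = 3))
  expect_equal(pearson_detrended(pair$a, pair$b)$r, 1)
})

test_that("cross-band correlation increases with artifact weight", {
  flat <- function(seed) {
    diurnal_sim_config(n_days = 15, day_level = 3, night_level = 3,
                       noise_cv = 0.3, seed = seed)
  }
  mean_r <- function(w) {
    mean(vapply(1:20, function(k) {
      pair <- generate_dual_band_series(
        dual_band_sim_config(flat(k), flat(k + 300), artifact_weight = w,
                             seed = 4000 + 100 * k))
      pearson_detrended(pair$a, pair$b)$r
    }, numeric(1)))
  }
  rs <- vapply(c(0.2, 0.5, 0.8), mean_r, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("sleep diary matches the window, jitter bound and day count", {
  cfg <- std_config(n_days = 21)
  d0 <- generate_sleep_diary(cfg, jitter = 0, seed = 1)
  expect_identical(nrow(d0), 21L)
  expect_true(all(d0$bed_time == "00:00:00"))
  expect_true(all(d0$rise_time == "06:00:00"))

  dj <- generate_sleep_diary(cfg, jitter = 1800, seed = 2)
  bed_s <- vapply(strsplit(dj$bed_time, ":"), function(p) {
    sum(as.numeric(p) * c(3600, 60, 1))
  }, numeric(1))
  rise_s <- vapply(strsplit(dj$rise_time, ":"), function(p) {
    sum(as.numeric(p) * c(3600, 60, 1))
  }, numeric(1))
  # bed jitters around midnight (wraps to 86400 - x)
  expect_true(all(pmin(bed_s, 86400 - bed_s) <= 1800))
  expect_true(all(abs(rise_s - 6 * 3600) <= 1800))
})

test_that("LFP generator is deterministic and annotates verbatim", {
  ep <- data.frame(label = "walk", start_s = 2, end_s = 4, amplitude = 10)
  cfg <- lfp_sim_config(duration = 6, artifact_epochs = ep, seed = 8)
  g1 <- generate_lfp_stream(cfg)
  g2 <- generate_lfp_stream(cfg)
  expect_identical(g1$stream$samples, g2$stream$samples)
  expect_identical(g1$annotations$label, "walk")
  expect_error(
    lfp_sim_config(duration = 6, artifact_epochs = data.frame(
      label = c("walk", "walk"), start_s = c(1, 2), end_s = c(3, 4),
      amplitude = 5), seed = 1),
    "overlapping")
})

test_that("without an oscillation the spectrum shows no beta peak", {
  cfg <- lfp_sim_config(duration = 120, beta_amp = 0, noise_amp = 2,
                        seed = 21)
  st <- generate_lfp_stream(cfg)$stream
  sp <- welch_spectrum(st)
  in_beta <- sp$freq >= 17 & sp$freq <= 23
  flank <- (sp$freq >= 10 & sp$freq < 15) | (sp$freq > 25 & sp$freq <= 35)
  expect_lt(mean(sp$psd[in_beta]) / mean(sp$psd[flank]), 1.6)

  # with a strong oscillation the same ratio is large
  cfg2 <- lfp_sim_config(duration = 120, beta_amp = 8, noise_amp = 2,
                         seed = 21)
  sp2 <- welch_spectrum(generate_lfp_stream(cfg2)$stream)
  expect_gt(mean(sp2$psd[sp2$freq >= 17 & sp2$freq <= 23]) /
              mean(sp2$psd[flank]), 10)
})

test_that("a pure sinusoid concentrates its 4-98 Hz power in a 5 Hz window", {
  cfg <- lfp_sim_config(duration = 30, beta_peak_freq = 20, beta_amp = 5,
                        noise_amp = 0, seed = 2)
  st <- generate_lfp_stream(cfg)$stream
  in_band <- band_power(st, list(low = 17.5, high = 22.5))
  total <- band_power(st, list(low = 4, high = 98))
  # power ratio, not amplitude ratio
  expect_gt(in_band^2 / total^2, 0.99)
})

test_that("artifact epochs raise in-epoch theta power above rest", {
  ep <- data.frame(label = c("rest", "head shake"),
                   start_s = c(0, 60), end_s = c(60, 90),
                   amplitude = c(0, 15))
  cfg <- lfp_sim_config(duration = 90, beta_amp = 4, noise_amp = 2,
                        artifact_epochs = ep, seed = 5)
  g <- generate_lfp_stream(cfg)
  fs <- g$stream$sample_rate
  theta <- list(low = 4, high = 8)
  seg <- function(a, b) {
    lfp_stream(g$stream$samples[(a * fs + 1):(b * fs)], sample_rate = fs)
  }
  expect_gt(band_power(seg(60, 90), theta), band_power(seg(0, 60), theta))
})
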