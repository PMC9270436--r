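#' Configuration for a synthetic chronic band-power stream
#'
#' Describes a simulated weeks-long chronic sensing recording: a
#' deterministic diurnal power profile (a day level and a night level
#' joined by logistic ramps around a sleep window, optionally modulated by
#' a smooth 24-h sinusoid and a slow linear drift) multiplied by
#' lognormal noise, with sporadic extreme outlier spikes. Power is
#' non-negative and right-skewed in real chronic logs, hence the
#' multiplicative lognormal noise model; `noise_cv` is its coefficient of
#' variation (the lognormal is scaled to mean 1, so the noise-free profile
#' is also the expected value).
#'
#' @param n_days Number of simulated days (>= 1).
#' @param sample_interval Sampling interval in seconds; must divide 24 h
#'   (default 600 s = 10 min, the chronic sensing rate).
#' @param day_level,night_level Expected power (uVp) outside / inside the
#'   sleep window; both > 0.
#' @param sleep_window Length-2 clock times `c(start, end)` as `"HH:MM"`
#'   strings (default `c("00:00", "06:00")`); may cross midnight.
#' @param transition_width Width (s) of the logistic sleep/wake ramp
#'   (default 1800 s); 0 gives a hard step.
#' @param circadian_amp Amplitude (fraction of level, in `[0, 1)`) of an
#'   optional smooth 24-h cosine multiplier peaking mid-afternoon (15:00).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise (>= 0).
#' @param outlier_rate Per-sample probability of an extreme spike, in
#'   `[0, 1)`.
#' @param outlier_scale Spike magnitude as a multiple of `day_level`.
#' @param drift_per_day Fractional linear drift per day (e.g. 0.01 = +1%
#'   per day).
#' @param seed Integer seed; mandatory, no global random state is used.
#' @param start_date Local civil date of the first sample (`"YYYY-MM-DD"`).
#' @param tz Timezone of the simulated device clock (default `"UTC"`).
#' @param subject_id,hemisphere,band Metadata forwarded to the series.
#'
#' @return A `diurnal_sim_config` list.
#' @seealso [generate_diurnal_series()], [diurnal_variance_fraction()]
#' @export
diurnal_sim_config <- function(n_days,
                               sample_interval = 600,
                               day_level = 4,
                               night_level = 2,
                               sleep_window = c("00:00", "06:00"),
                               transition_width = 1800,
                               circadian_amp = 0,
                               noise_cv = 0.2,
                               outlier_rate = 0,
                               outlier_scale = 10,
                               drift_per_day = 0,
                               seed = 1L,
                               start_date = "2021-06-01",
                               tz = "UTC",
                               subject_id = "sim",
                               hemisphere = "left",
                               band = list(center_hz = 20, width_hz = 5,
                                           name = "beta")) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  chk(is.numeric(n_days) && n_days >= 1, "n_days", "must be >= 1")
  chk(86400 %% sample_interval == 0, "sample_interval",
      "must divide 24 h")
  chk(day_level > 0, "day_level", "must be > 0")
  chk(night_level > 0, "night_level", "must be > 0")
  chk(noise_cv >= 0, "noise_cv", "must be >= 0")
  chk(outlier_rate >= 0 && outlier_rate < 1, "outlier_rate",
      "must be in [0, 1)")
  chk(transition_width >= 0, "transition_width", "must be >= 0")
  chk(circadian_amp >= 0 && circadian_amp < 1, "circadian_amp",
      "must be in [0, 1)")
  chk(length(sleep_window) == 2L, "sleep_window",
      "must be c(start, end) clock times")
  win <- clock_to_seconds(sleep_window)
  dur <- (win[2] - win[1]) %% 86400
  chk(dur > 0 && dur <= 43200, "sleep_window",
      "must span more than 0 and at most 12 hours")
  structure(
    list(n_days = as.integer(n_days), sample_interval = sample_interval,
         day_level = day_level, night_level = night_level,
         sleep_window = sleep_window, transition_width = transition_width,
         circadian_amp = circadian_amp, noise_cv = noise_cv,
         outlier_rate = outlier_rate, outlier_scale = outlier_scale,
         drift_per_day = drift_per_day, seed = seed,
         start_date = start_date, tz = tz, subject_id = subject_id,
         hemisphere = hemisphere, band = band),
    class = "diurnal_sim_config"
  )
}

# "HH:MM" or "HH:MM:SS" -> seconds since midnight
clock_to_seconds <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) == 2L) p <- c(p, 0)
    if (anyNA(p) || length(p) != 3L) {
      stop("bad clock time; expected 'HH:MM' or 'HH:MM:SS'", call. = FALSE)
    }
    p[1] * 3600 + p[2] * 60 + p[3]
  }, numeric(1))
}

seconds_to_clock <- function(s) {
  s <- round(s) %% 86400
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

# Sleep-membership weight in [0,1] at clock second t: logistic ramps of
# width `width` at the window edges, computed on circular signed clock
# distances so the weight is continuous across midnight. Assumes the
# window spans at most 12 h (enforced by the config constructor).
sleep_weight <- function(t, window_sec, width) {
  s <- window_sec[1]; e <- window_sec[2]
  d_in <- ((t - s + 43200) %% 86400) - 43200   # signed distance past start
  d_out <- ((e - t + 43200) %% 86400) - 43200  # signed distance before end
  if (width <= 0) {
    as.numeric(d_in >= 0 & d_out > 0)  # hard step on [start, end)
  } else {
    stats::plogis(d_in / (width / 4)) * stats::plogis(d_out / (width / 4))
  }
}

# Deterministic expected power at clock second t on day d (0-based).
noise_free_level <- function(config, t, d = 0) {
  w <- sleep_weight(t, clock_to_seconds(config$sleep_window),
                    config$transition_width)
  level <- config$day_level +
    (config$night_level - config$day_level) * w
  if (config$circadian_amp > 0) {
    level <- level *
      (1 + config$circadian_amp * cos(2 * pi * (t - 15 * 3600) / 86400))
  }
  level * (1 + config$drift_per_day * d)
}

#' Closed-form diurnal variance fraction of a simulated stream
#'
#' For a drift-free configuration, the fraction of total variance
#' attributable to clock time is available in closed form: with
#' noise-free profile p(t) over one day and lognormal noise of
#' coefficient of variation c, the time-of-day component contributes
#' Var(p) and the noise contributes E(p^2) c^2, so the fraction is
#' Var(p) / (Var(p) + E(p^2) c^2). This is the ground truth that
#' [variance_explained()] should recover on generated data.
#'
#' `noise_cv_for_fraction()` inverts the relation: it returns the
#' `noise_cv` that makes the diurnal component account for a requested
#' fraction of total variance.
#'
#' @param config A [diurnal_sim_config()] (drift is ignored).
#' @return `diurnal_variance_fraction()`: the fraction in `[0, 1]`.
#' @export
diurnal_variance_fraction <- function(config) {
  t <- seq(0, 86400 - config$sample_interval, by = config$sample_interval)
  p <- noise_free_level(config, t, d = 0)
  var_p <- mean(p^2) - mean(p)^2
  var_p / (var_p + mean(p^2) * config$noise_cv^2)
}

#' @rdname diurnal_variance_fraction
#' @param fraction Target diurnal variance fraction in (0, 1).
#' @return `noise_cv_for_fraction()`: the corresponding `noise_cv`.
#' @export
noise_cv_for_fraction <- function(config, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  t <- seq(0, 86400 - config$sample_interval, by = config$sample_interval)
  p <- noise_free_level(config, t, d = 0)
  var_p <- mean(p^2) - mean(p)^2
  if (var_p == 0) stop("profile is flat; no fraction is attainable",
                       call. = FALSE)
  sqrt(var_p * (1 - fraction) / (fraction * mean(p^2)))
}

#' Generate a synthetic chronic band-power series
#'
#' Produces `n_days` x (24 h / `sample_interval`) samples on a regular
#' grid starting at local midnight of `start_date`, following the model
#' described in [diurnal_sim_config()]. Identical seeds give bit-identical
#' output.
#'
#' @param config A [diurnal_sim_config()].
#' @return A [band_power_series] with attribute `"truth"` holding the
#'   noise-free profile, outlier indices and the config.
#' @export
#'
#' @examples
#' cfg <- diurnal_sim_config(n_days = 3, noise_cv = 0.1, seed = 7)
#' s <- generate_diurnal_series(cfg)
#' length(s)  # 3 * 144
generate_diurnal_series <- function(config) {
  stopifnot(inherits(config, "diurnal_sim_config"))
  per_day <- 86400 %/% config$sample_interval
  n <- config$n_days * per_day
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = config$tz)
  ts <- t0 + config$sample_interval * (0:(n - 1))
  clock <- (config$sample_interval * (0:(n - 1))) %% 86400
  day_idx <- (config$sample_interval * (0:(n - 1))) %/% 86400
  level <- noise_free_level(config, clock, day_idx)
  vals <- with_seed(config$seed, {
    v <- level
    if (config$noise_cv > 0) {
      sig <- sqrt(log(1 + config$noise_cv^2))
      v <- v * rlnorm(n, meanlog = -sig^2 / 2, sdlog = sig)
    }
    out_idx <- integer(0)
    if (config$outlier_rate > 0) {
      out_idx <- which(runif(n) < config$outlier_rate)
      v[out_idx] <- config$outlier_scale * config$day_level
    }
    list(v = v, out_idx = out_idx)
  })
  series <- band_power_series(
    ts, vals$v, subject_id = config$subject_id,
    hemisphere = config$hemisphere, band = config$band,
    sample_interval = config$sample_interval
  )
  attr(series, "truth") <- list(noise_free = level,
                                outlier_indices = vals$out_idx,
                                config = config)
  series
}

#' Configuration for a concurrently sampled dual-band stream pair
#'
#' Models the frequency-specificity recording setup: two bands (e.g. beta
#' from one hemisphere, theta from the other) logged on an identical
#' timestamp grid. Each band follows its own [diurnal_sim_config()]; in
#' addition, a fraction `artifact_weight` of each band's log-noise
#' variance is drawn from a process shared between the bands (emulating
#' broadband artifacts that hit both hemispheres at once), and an optional
#' daytime burst process multiplies both bands simultaneously (emulating
#' clustered movement/dyskinesia artifacts, which make the daytime value
#' distribution bimodal).
#'
#' @param base_a,base_b [diurnal_sim_config()]s for the two bands; must
#'   agree on `n_days`, `sample_interval`, `start_date` and `tz`.
#' @param artifact_weight Fraction in `[0, 1]` of log-noise variance that
#'   is shared between bands.
#' @param artifact_burst_rate Expected bursts per waking hour (default 0).
#' @param artifact_burst_duration Mean burst duration in seconds
#'   (exponentially distributed).
#' @param artifact_burst_scale Multiplicative power elevation during a
#'   burst (applied to both bands).
#' @param seed Integer seed for the shared and band-specific noise.
#' @return A `dual_band_sim_config` list.
#' @export
dual_band_sim_config <- function(base_a, base_b,
                                 artifact_weight = 0,
                                 artifact_burst_rate = 0,
                                 artifact_burst_duration = 1800,
                                 artifact_burst_scale = 4,
                                 seed = 1L) {
  stopifnot(inherits(base_a, "diurnal_sim_config"),
            inherits(base_b, "diurnal_sim_config"))
  if (base_a$n_days != base_b$n_days) {
    stop("invalid `base_b`: n_days differs between band configs",
         call. = FALSE)
  }
  if (base_a$sample_interval != base_b$sample_interval ||
      base_a$start_date != base_b$start_date || base_a$tz != base_b$tz) {
    stop("band configs must share sample_interval, start_date and tz",
         call. = FALSE)
  }
  if (artifact_weight < 0 || artifact_weight > 1) {
    stop("invalid `artifact_weight`: must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(base_a = base_a, base_b = base_b,
         artifact_weight = artifact_weight,
         artifact_burst_rate = artifact_burst_rate,
         artifact_burst_duration = artifact_burst_duration,
         artifact_burst_scale = artifact_burst_scale,
         seed = seed),
    class = "dual_band_sim_config"
  )
}

#' Generate a concurrently sampled dual-band series pair
#'
#' @param config A [dual_band_sim_config()].
#' @return A list with [band_power_series] elements `a` and `b` (identical
#'   timestamp grids) and a data frame `bursts` of shared artifact
#'   episodes (`start`, `end`, POSIXct).
#' @export
generate_dual_band_series <- function(config) {
  stopifnot(inherits(config, "dual_band_sim_config"))
  ca <- config$base_a; cb <- config$base_b
  per_day <- 86400 %/% ca$sample_interval
  n <- ca$n_days * per_day
  t0 <- as.POSIXct(paste(ca$start_date, "00:00:00"), tz = ca$tz)
  ts <- t0 + ca$sample_interval * (0:(n - 1))
  clock <- (ca$sample_interval * (0:(n - 1))) %% 86400
  day_idx <- (ca$sample_interval * (0:(n - 1))) %/% 86400
  w <- config$artifact_weight

  res <- with_seed(config$seed, {
    z_shared <- rnorm(n)
    z_a <- rnorm(n)
    z_b <- rnorm(n)
    # daytime burst process: Poisson starts in the waking window of band a,
    # exponential durations, multiplying both bands
    bursts <- data.frame(start = numeric(0), end = numeric(0))
    burst_on <- rep(FALSE, n)
    if (config$artifact_burst_rate > 0) {
      win <- clock_to_seconds(ca$sleep_window)
      wake_h <- ((win[1] - win[2]) %% 86400) / 3600
      elapsed <- ca$sample_interval * (0:(n - 1))
      for (d in seq_len(ca$n_days) - 1L) {
        k <- stats::rpois(1, config$artifact_burst_rate * wake_h)
        if (k == 0) next
        wake0 <- d * 86400 + win[2]  # waking starts at sleep-window end
        starts <- wake0 + runif(k) * wake_h * 3600
        durs <- rexp(k, 1 / config$artifact_burst_duration)
        for (j in seq_len(k)) {
          burst_on <- burst_on |
            (elapsed >= starts[j] & elapsed < starts[j] + durs[j])
        }
        bursts <- rbind(bursts,
                        data.frame(start = starts, end = starts + durs))
      }
    }
    make_band <- function(cfg, z_own) {
      level <- noise_free_level(cfg, clock, day_idx)
      v <- level
      if (cfg$noise_cv > 0) {
        sig <- sqrt(log(1 + cfg$noise_cv^2))
        z <- sqrt(w) * z_shared + sqrt(1 - w) * z_own
        v <- v * exp(sig * z - sig^2 / 2)
      }
      v[burst_on] <- v[burst_on] * config$artifact_burst_scale
      band_power_series(ts, v, subject_id = cfg$subject_id,
                        hemisphere = cfg$hemisphere, band = cfg$band,
                        sample_interval = cfg$sample_interval)
    }
    list(a = make_band(ca, z_a), b = make_band(cb, z_b), bursts = bursts)
  })
  if (nrow(res$bursts)) {
    res$bursts <- data.frame(start = t0 + res$bursts$start,
                             end = t0 + res$bursts$end)
  } else {
    res$bursts <- data.frame(start = as.POSIXct(character(0), tz = ca$tz),
                             end = as.POSIXct(character(0), tz = ca$tz))
  }
  res
}

#' Generate a synthetic sleep diary
#'
#' One bed/rise entry per simulated day, equal to the configuration's
#' sleep window plus independent uniform jitter on each bound.
#'
#' @param config A [diurnal_sim_config()].
#' @param jitter Maximum absolute jitter in seconds (uniform on
#'   `[-jitter, jitter]`; default 0).
#' @param seed Integer seed.
#' @return A `sleep_diary` data frame with columns `date` (the civil date
#'   the in-bed interval starts on), `bed_time`, `rise_time`
#'   (`"HH:MM:SS"` local clock). Intervals whose rise time is not after
#'   the bed time cross midnight into the next date.
#' @export
generate_sleep_diary <- function(config, jitter = 0, seed = 1L) {
  stopifnot(inherits(config, "diurnal_sim_config"), jitter >= 0)
  win <- clock_to_seconds(config$sleep_window)
  n <- config$n_days
  jit <- with_seed(seed, {
    if (jitter > 0) {
      matrix(runif(2 * n, -jitter, jitter), ncol = 2)
    } else {
      matrix(0, nrow = n, ncol = 2)
    }
  })
  dates <- as.Date(config$start_date) + (seq_len(n) - 1L)
  structure(
    data.frame(date = dates,
               bed_time = seconds_to_clock(win[1] + jit[, 1]),
               rise_time = seconds_to_clock(win[2] + jit[, 2]),
               stringsAsFactors = FALSE),
    class = c("sleep_diary", "data.frame")
  )
}
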