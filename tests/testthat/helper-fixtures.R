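# Build a series on a regular grid from bare values.
make_series <- function(values, start = "2021-06-01", tz = "UTC",
                        interval = 600, ...) {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = tz)
  band_power_series(t0 + interval * (seq_along(values) - 1L), values,
                    sample_interval = interval, ...)
}

# Series whose values sit exactly at 30-min bin centers and depend only on
# the bin: the time-of-day fit reproduces it exactly.
make_bin_center_series <- function(bin_values, n_days = 2,
                                   start = "2021-06-01", tz = "UTC") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = tz)
  offs <- 900 + 1800 * (seq_along(bin_values) - 1L)
  ts <- as.vector(outer(offs, 86400 * (seq_len(n_days) - 1L), "+"))
  band_power_series(t0 + sort(ts), rep(bin_values, n_days),
                    sample_interval = 1800, check_nonneg = FALSE)
}

# Standard 30-day diurnal config used across tests.
std_config <- function(..., n_days = 30, seed = 1L) {
  diurnal_sim_config(n_days = n_days, day_level = 4, night_level = 2,
                     sleep_window = c("00:00", "06:00"), seed = seed, ...)
}
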