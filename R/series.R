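#' Chronic band-power series
#'
#' A `band_power_series` holds one hemisphere's chronically sensed band-power
#' stream: one power value (microvolt-peak, uVp) per nominal sampling
#' interval (10 minutes on current sensing devices), with timezone-aware
#' timestamps. It is the common currency of the whole package: the
#' preprocessing, diurnal-statistics and epoch-alignment stages all consume
#' and return this class.
#'
#' @param timestamps `POSIXct` vector, strictly increasing. The attached
#'   timezone defines civil ("clock") time for all day-based operations;
#'   use [to_local_time()] to re-label device UTC stamps.
#' @param values Numeric vector of band-power readings, same length as
#'   `timestamps`. Must be finite. Raw power must be non-negative;
#'   derived series (z-scores, residuals) may be negative, so the
#'   constructor only enforces non-negativity when `check_nonneg = TRUE`.
#' @param subject_id Subject label.
#' @param hemisphere `"left"` or `"right"` (or `NA` when not applicable).
#' @param band List with elements `center_hz`, `width_hz`, `name` (e.g.
#'   `"beta"`, `"theta"`).
#' @param sample_interval Nominal sampling interval in seconds (default 600).
#' @param check_nonneg Enforce `values >= 0` (default `TRUE`; set to
#'   `FALSE` for derived series such as z-scores).
#'
#' @return An object of class `band_power_series`.
#' @export
#'
#' @examples
#' ts <- as.POSIXct("2021-06-01 00:00", tz = "UTC") + 600 * (0:5)
#' band_power_series(ts, c(2, 2.2, 1.9, 4, 4.1, 3.8), subject_id = "sim")
band_power_series <- function(timestamps, values,
                              subject_id = "unknown",
                              hemisphere = NA_character_,
                              band = list(center_hz = 20, width_hz = 5,
                                          name = "beta"),
                              sample_interval = 600,
                              check_nonneg = TRUE) {
  if (!inherits(timestamps, "POSIXct")) {
    stop("`timestamps` must be POSIXct", call. = FALSE)
  }
  if (length(timestamps) != length(values)) {
    stop("`timestamps` and `values` must have equal length", call. = FALSE)
  }
  if (anyNA(timestamps)) stop("`timestamps` contains NA", call. = FALSE)
  if (length(timestamps) > 1L && any(diff(as.numeric(timestamps)) <= 0)) {
    stop("`timestamps` must be strictly increasing", call. = FALSE)
  }
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop("`values` must all be finite", call. = FALSE)
  }
  if (check_nonneg && any(values < 0)) {
    stop("`values` must be non-negative (band power)", call. = FALSE)
  }
  structure(
    list(timestamps = timestamps, values = values,
         subject_id = subject_id, hemisphere = hemisphere, band = band,
         sample_interval = as.numeric(sample_interval)),
    class = "band_power_series"
  )
}

#' @export
print.band_power_series <- function(x, ...) {
  tz <- attr(x$timestamps, "tzone") %||% "UTC"
  cat(sprintf("<band_power_series> %s / %s / %s band\n",
              x$subject_id, x$hemisphere, x$band$name))
  cat(sprintf("  %d samples @ %g s, %s .. %s (%s)\n",
              length(x$values), x$sample_interval,
              format(min(x$timestamps)), format(max(x$timestamps)),
              tz))
  cat(sprintf("  values: median %.3g, range [%.3g, %.3g]\n",
              stats::median(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.band_power_series <- function(x) length(x$values)

#' @export
as.data.frame.band_power_series <- function(x, ...) {
  data.frame(timestamp = x$timestamps, value = x$values)
}

# Replace values, keeping all metadata. Derived series may be negative.
series_with_values <- function(series, values) {
  series$values <- as.numeric(values)
  stopifnot(length(series$values) == length(series$timestamps))
  series
}

series_tz <- function(series) {
  attr(series$timestamps, "tzone") %||% "UTC"
}

# Seconds since local midnight for each sample, in the series' own zone.
clock_seconds <- function(series) {
  lt <- as.POSIXlt(series$timestamps, tz = series_tz(series))
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

# Local civil date label (YYYY-MM-DD) per sample.
local_dates <- function(series) {
  format(series$timestamps, "%Y-%m-%d", tz = series_tz(series))
}
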