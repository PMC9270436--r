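#' Iterative z-score outlier interpolation
#'
#' Chronic band-power logs contain sporadic extreme values whose underlying
#' LFP cannot be recovered, so they are replaced rather than modelled: any
#' sample whose z-score (relative to the full series mean and sample SD)
#' exceeds `z_threshold` is replaced by linear interpolation between its
#' nearest non-outlier neighbours, and the pass is repeated with
#' recomputed mean/SD until no sample exceeds the threshold. Outliers at
#' the series ends, with no valid neighbour on one side, take the nearest
#' valid value.
#'
#' By default the rule is two-sided (`|z| > z_threshold`), since after
#' normalization spikes can deflect in either direction; `two_sided =
#' FALSE` restricts it to positive excursions.
#'
#' The operation is idempotent and never changes the series length or
#' timestamps. A zero-variance series is returned unchanged.
#'
#' @param series A [band_power_series] of length >= 3.
#' @param z_threshold Replacement threshold on the z-score (default 6).
#' @param two_sided Use `|z|` (default) rather than `z` alone.
#' @return A list with elements `series` (cleaned) and `report`, the
#'   latter a `preprocess_report` with `n_outliers_replaced`,
#'   `n_iterations` and `replaced_indices`.
#' @export
#'
#' @examples
#' ts <- as.POSIXct("2021-06-01", tz = "UTC") + 600 * (0:99)
#' x <- rep(1, 100); x[50] <- 40
#' out <- remove_outliers(band_power_series(ts, x))
#' out$report$n_outliers_replaced
remove_outliers <- function(series, z_threshold = 6, two_sided = TRUE) {
  stopifnot(inherits(series, "band_power_series"))
  if (length(series) < 3L) {
    stop("series must have at least 3 samples", call. = FALSE)
  }
  x <- series$values
  replaced <- integer(0)
  n_iter <- 0L
  repeat {
    s <- sd(x)
    if (!is.finite(s) || s == 0) break
    z <- (x - mean(x)) / s
    bad <- if (two_sided) abs(z) > z_threshold else z > z_threshold
    if (!any(bad)) break
    n_iter <- n_iter + 1L
    good_idx <- which(!bad)
    if (length(good_idx) < 2L) {
      stop("outlier removal left fewer than 2 valid samples", call. = FALSE)
    }
    bad_idx <- which(bad)
    # rule = 2: endpoint outliers take the nearest valid value
    x[bad_idx] <- approx(good_idx, x[good_idx], xout = bad_idx, rule = 2)$y
    replaced <- union(replaced, bad_idx)
  }
  report <- structure(
    list(n_outliers_replaced = length(replaced),
         n_iterations = n_iter,
         replaced_indices = sort(replaced)),
    class = "preprocess_report"
  )
  list(series = series_with_values(series, x), report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("<preprocess_report> %d outlier(s) replaced in %d pass(es)\n",
              x$n_outliers_replaced, x$n_iterations))
  invisible(x)
}

#' z-score a band-power series
#'
#' Standardizes values to mean 0 and sample SD 1 (n - 1 denominator), the
#' form used for visual comparison across subjects and hemispheres.
#'
#' @param series A [band_power_series].
#' @return A [band_power_series] of z-scores (values may be negative).
#' @export
zscore_series <- function(series) {
  stopifnot(inherits(series, "band_power_series"))
  s <- sd(series$values)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a zero-variance series", call. = FALSE)
  }
  out <- series_with_values(series, (series$values - mean(series$values)) / s)
  out$band$name <- paste0(series$band$name, "_z")
  out
}

#' Daily detrending
#'
#' Removes slow multi-day drift by dividing every sample by its own civil
#' day's central statistic, so that (with the default `"median"`) each
#' day's detrended median is exactly 1. Days run midnight-to-midnight in
#' the series' attached timezone. The `"mean"` variant (per-day mean = 1)
#' is used when detrended series feed a correlation analysis.
#'
#' @param series A [band_power_series]; re-label with [to_local_time()]
#'   first if the device logged UTC.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return The detrended [band_power_series] (dimensionless values).
#' @export
detrend_daily <- function(series, statistic = c("median", "mean")) {
  stopifnot(inherits(series, "band_power_series"))
  statistic <- match.arg(statistic)
  day <- local_dates(series)
  fun <- if (statistic == "median") median else mean
  day_stat <- tapply(series$values, day, fun)
  if (any(day_stat == 0)) {
    bad <- names(day_stat)[day_stat == 0][1L]
    stop("daily ", statistic, " is zero on ", bad, call. = FALSE)
  }
  series_with_values(series, series$values / as.numeric(day_stat[day]))
}
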