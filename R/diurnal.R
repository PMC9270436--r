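# ---- internal clock-time machinery ---------------------------------------

# 0-based bin index for clock seconds
clock_bin <- function(clock, bin_width) as.integer(clock %/% bin_width)

# Per-bin statistic over all samples; returns full-length vectors with NA
# for empty bins.
bin_statistic <- function(values, clock, bin_width, fun) {
  n_bins <- as.integer(86400 / bin_width)
  idx <- clock_bin(clock, bin_width)
  out <- rep(NA_real_, n_bins)
  cnt <- integer(n_bins)
  tab <- tapply(values, factor(idx, levels = 0:(n_bins - 1)), fun)
  out[] <- as.numeric(tab)
  cnt[] <- as.integer(table(factor(idx, levels = 0:(n_bins - 1))))
  list(stat = out, count = cnt,
       centers = (0:(n_bins - 1) + 0.5) * bin_width)
}

# Fast per-bin means (the inner loop of the shuffle test).
bin_means_fast <- function(values, bin_idx, n_bins) {
  i1 <- bin_idx + 1L
  sums <- rowsum(values, i1, reorder = FALSE)
  lev <- as.integer(rownames(sums))
  out <- rep(NA_real_, n_bins)
  out[lev] <- sums[, 1L]
  cnt <- tabulate(i1, nbins = n_bins)
  out / ifelse(cnt == 0, NA_real_, cnt)
}

# Evaluate a piecewise-linear interpolation of bin means at arbitrary clock
# times. Empty (NA) bins are interpolated across. `wrap = TRUE` treats the
# clock as circular (interpolating across midnight); otherwise values
# beyond the first/last occupied bin centers are held constant.
interp_bins <- function(bin_values, centers, clock, wrap = TRUE) {
  ok <- !is.na(bin_values)
  if (sum(ok) < 2L) {
    stop("need at least 2 non-empty clock-time bins", call. = FALSE)
  }
  x <- centers[ok]; y <- bin_values[ok]
  if (wrap) {
    m <- length(x)
    x <- c(x[m] - 86400, x, x[1] + 86400)
    y <- c(y[m], y, y[1])
    approx(x, y, xout = clock)$y
  } else {
    approx(x, y, xout = clock, rule = 2)$y
  }
}

# ---- diurnal profile ------------------------------------------------------

#' Binned diurnal profile
#'
#' Summarizes a (detrended) series around the 24-h cycle: a central
#' statistic of all values falling in each clock-time bin, pooled across
#' days. This is the quantity displayed in circular ("rose") diurnal
#' plots. With `per_day_first = TRUE` the statistic is computed in two
#' stages — per-day bin medians first, then the median across days — which
#' weights every day equally regardless of missing samples.
#'
#' @param series A [band_power_series], normally detrended with
#'   [detrend_daily()] first.
#' @param bin_width Bin width in seconds; must divide 24 h (default 1800 s
#'   = 30 min, giving 48 bins).
#' @param statistic `"median"` (default) or `"mean"`.
#' @param per_day_first Two-stage (per-day, then across-day) statistic.
#' @return A `diurnal_profile`: list with `bin_centers` (clock seconds),
#'   `stat_per_bin`, `count_per_bin`, `bin_width`, `statistic`.
#' @export
diurnal_profile <- function(series, bin_width = 1800,
                            statistic = c("median", "mean"),
                            per_day_first = FALSE) {
  stopifnot(inherits(series, "band_power_series"))
  statistic <- match.arg(statistic)
  if (86400 %% bin_width != 0) {
    stop("`bin_width` must divide 24 h", call. = FALSE)
  }
  fun <- if (statistic == "median") median else mean
  clock <- clock_seconds(series)
  if (per_day_first) {
    day <- local_dates(series)
    n_bins <- as.integer(86400 / bin_width)
    idx <- clock_bin(clock, bin_width)
    per_day <- tapply(series$values,
                      list(factor(idx, levels = 0:(n_bins - 1)), day), fun)
    stat <- apply(per_day, 1L, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) NA_real_ else fun(r)
    })
    cnt <- as.integer(table(factor(idx, levels = 0:(n_bins - 1))))
    bs <- list(stat = unname(stat), count = cnt,
               centers = (0:(n_bins - 1) + 0.5) * bin_width)
  } else {
    bs <- bin_statistic(series$values, clock, bin_width, fun)
  }
  structure(
    list(bin_centers = bs$centers, stat_per_bin = bs$stat,
         count_per_bin = bs$count, bin_width = bin_width,
         statistic = statistic, per_day_first = per_day_first),
    class = "diurnal_profile"
  )
}

#' @export
print.diurnal_profile <- function(x, ...) {
  cat(sprintf("<diurnal_profile> %d bins of %g min (%s%s)\n",
              length(x$bin_centers), x$bin_width / 60, x$statistic,
              if (x$per_day_first) ", per-day first" else ""))
  invisible(x)
}

#' @export
as.data.frame.diurnal_profile <- function(x, ...) {
  data.frame(clock = seconds_to_clock(x$bin_centers),
             bin_center_s = x$bin_centers,
             stat = x$stat_per_bin, count = x$count_per_bin)
}

# ---- time-of-day fit ------------------------------------------------------

#' Time-of-day fit
#'
#' The day is divided into fixed clock-time bins (default 30 min) and the
#' mean value in each bin, pooled across all days, is the fit estimate at
#' that bin's center; between centers the fit is evaluated by linear
#' interpolation. Empty bins are interpolated across. Because clock time
#' is circular, interpolation wraps across midnight by default;
#' `wrap = FALSE` holds the fit constant beyond the outermost occupied
#' bin centers instead.
#'
#' @param series A [band_power_series].
#' @param bin_width Bin width in seconds (must divide 24 h; default 1800).
#' @param wrap Interpolate circularly across midnight (default `TRUE`).
#' @return A `time_of_day_fit`: `bin_centers`, `bin_means`,
#'   `count_per_bin`, `bin_width`, `wrap`. Evaluate it with
#'   [predict_time_of_day()].
#' @export
fit_time_of_day <- function(series, bin_width = 1800, wrap = TRUE) {
  stopifnot(inherits(series, "band_power_series"))
  if (86400 %% bin_width != 0) {
    stop("`bin_width` must divide 24 h", call. = FALSE)
  }
  clock <- clock_seconds(series)
  bs <- bin_statistic(series$values, clock, bin_width, mean)
  if (sum(!is.na(bs$stat)) < 2L) {
    stop("all samples fall in a single clock-time bin; cannot fit",
         call. = FALSE)
  }
  structure(
    list(bin_centers = bs$centers, bin_means = bs$stat,
         count_per_bin = bs$count, bin_width = bin_width, wrap = wrap),
    class = "time_of_day_fit"
  )
}

#' Evaluate a time-of-day fit at clock times
#'
#' At a bin center the fit returns that bin's mean exactly; elsewhere the
#' linear interpolation described in [fit_time_of_day()].
#'
#' @param fit A `time_of_day_fit`.
#' @param clock Clock times in seconds since local midnight (vector).
#' @return Fitted values.
#' @export
predict_time_of_day <- function(fit, clock) {
  stopifnot(inherits(fit, "time_of_day_fit"))
  interp_bins(fit$bin_means, fit$bin_centers, clock %% 86400,
              wrap = fit$wrap)
}

#' @export
print.time_of_day_fit <- function(x, ...) {
  cat(sprintf("<time_of_day_fit> %d bins of %g min (%s midnight)\n",
              length(x$bin_centers), x$bin_width / 60,
              if (x$wrap) "wraps" else "does not wrap"))
  invisible(x)
}

# ---- variance explained ---------------------------------------------------

# Core VE computation shared by the public functions and the shuffle test.
ve_of <- function(values, clock, bin_width, wrap = TRUE) {
  n_bins <- as.integer(86400 / bin_width)
  idx <- clock_bin(clock, bin_width)
  means <- bin_means_fast(values, idx, n_bins)
  centers <- (0:(n_bins - 1) + 0.5) * bin_width
  fitted <- interp_bins(means, centers, clock, wrap = wrap)
  vt <- var(values)
  vr <- var(values - fitted)
  list(ve = (vt - vr) / vt, var_total = vt, var_residual = vr)
}

#' Variance explained by time of day
#'
#' The influence of clock time is removed by subtracting the time-of-day
#' fit evaluated at each sample's clock time; the variance explained is
#' the total variance minus the residual variance, divided by the total
#' variance. Values can slightly exceed the in-bin R-squared or be
#' marginally negative on pathological inputs (the fit is interpolated,
#' not a projection); they are reported as-is.
#'
#' @param series A [band_power_series] with positive variance.
#' @param fit Optional `time_of_day_fit`; by default fitted from `series`
#'   itself. Supplying an external fit (e.g. from an unrelated series)
#'   gives a null-calibration check.
#' @param bin_width,wrap Passed to [fit_time_of_day()] when `fit` is NULL.
#' @return A `variance_explained`: `ve`, `var_total`, `var_residual`.
#' @export
variance_explained <- function(series, fit = NULL, bin_width = 1800,
                               wrap = TRUE) {
  stopifnot(inherits(series, "band_power_series"))
  vt <- var(series$values)
  if (!is.finite(vt) || vt == 0) {
    stop("series has zero total variance", call. = FALSE)
  }
  clock <- clock_seconds(series)
  if (is.null(fit)) {
    res <- ve_of(series$values, clock, bin_width, wrap)
  } else {
    fitted <- predict_time_of_day(fit, clock)
    vr <- var(series$values - fitted)
    res <- list(ve = (vt - vr) / vt, var_total = vt, var_residual = vr)
  }
  structure(res, class = "variance_explained")
}

#' @export
print.variance_explained <- function(x, ...) {
  cat(sprintf("<variance_explained> VE = %.4f (total %.4g, residual %.4g)\n",
              x$ve, x$var_total, x$var_residual))
  invisible(x)
}

#' Windowed variance explained
#'
#' Variance explained by time of day using only samples inside a clock
#' window (e.g. the waking window 08:00-20:00 or the sleep-dominated
#' window 00:00-06:00): the fit is built from, and the variances computed
#' over, in-window samples alone. A flat-within-window diurnal step
#' therefore yields near-zero windowed VE even when the full-24-h VE is
#' large. With the full-day window this equals [variance_explained()]
#' exactly.
#'
#' @param series A [band_power_series].
#' @param window Length-2 clock times `c(start, end)` (`"HH:MM"`); the
#'   window is `[start, end)` and may cross midnight.
#' @param bin_width,wrap As in [fit_time_of_day()].
#' @return A `variance_explained`.
#' @export
windowed_variance_explained <- function(series, window,
                                        bin_width = 1800, wrap = TRUE) {
  stopifnot(inherits(series, "band_power_series"))
  win <- clock_to_seconds(window)
  clock <- clock_seconds(series)
  inside <- if (win[1] < win[2]) {
    clock >= win[1] & clock < win[2]
  } else if (win[1] > win[2]) {
    clock >= win[1] | clock < win[2]
  } else {
    rep(TRUE, length(clock))  # degenerate window = full day
  }
  if (!any(inside)) stop("no samples inside the window", call. = FALSE)
  v <- series$values[inside]
  if (var(v) == 0) stop("zero variance inside the window", call. = FALSE)
  structure(ve_of(v, clock[inside], bin_width, wrap),
            class = "variance_explained")
}

# ---- temporal shuffling test ----------------------------------------------

#' Day-shift temporal shuffling test
#'
#' Permutation test for whether the observed variance explained by time
#' of day could arise by chance. Each surrogate applies an independent
#' circular shift, uniform over the day in steps of one nominal sample
#' interval, to each civil day's samples: days are offset relative to
#' each other while each day keeps its own temporal structure (samples
#' shifted past midnight wrap to the start of the same day). The variance
#' explained is recomputed for each surrogate with the same fit
#' procedure, giving a null distribution; the empirical p-value uses the
#' add-one correction, so the smallest attainable p with 1000 shuffles is
#' 1/1001 (reported in practice as p < 0.001).
#'
#' @param series A [band_power_series] spanning at least 2 civil days.
#' @param n_shuffles Number of surrogates (default 1000).
#' @param seed Integer seed (mandatory; the test is deterministic given
#'   it).
#' @param bin_width,wrap As in [fit_time_of_day()].
#' @return A `shuffle_test_result`: `observed_ve`, `null_ve` (length
#'   `n_shuffles`), `p_value`, `n_shuffles`, `seed`.
#' @export
temporal_shuffle_test <- function(series, n_shuffles = 1000, seed = 1L,
                                  bin_width = 1800, wrap = TRUE) {
  stopifnot(inherits(series, "band_power_series"))
  clock <- clock_seconds(series)
  day <- local_dates(series)
  days <- unique(day)
  if (length(days) < 2L) {
    stop("need at least 2 days of data", call. = FALSE)
  }
  day_id <- match(day, days)
  slots_per_day <- as.integer(86400 / series$sample_interval)
  obs <- ve_of(series$values, clock, bin_width, wrap)$ve
  vals <- series$values
  interval <- series$sample_interval
  null_ve <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      shifts <- sample.int(slots_per_day, length(days),
                           replace = TRUE) - 1L
      new_clock <- (clock + shifts[day_id] * interval) %% 86400
      ve_of(vals, new_clock, bin_width, wrap)$ve
    }, numeric(1))
  })
  p <- (1 + sum(null_ve >= obs)) / (1 + n_shuffles)
  structure(
    list(observed_ve = obs, null_ve = null_ve, p_value = p,
         n_shuffles = n_shuffles, seed = seed),
    class = "shuffle_test_result"
  )
}

#' @export
print.shuffle_test_result <- function(x, ...) {
  cat(sprintf(
    "<shuffle_test_result> VE = %.4f, p = %.4g (%d day-shift surrogates)\n",
    x$observed_ve, x$p_value, x$n_shuffles))
  if (x$p_value <= 1 / (1 + x$n_shuffles) + 1e-12) {
    cat("  (smallest attainable p at this shuffle count)\n")
  }
  invisible(x)
}

# ---- day x bin matrix -----------------------------------------------------

#' Day-by-bin matrix of detrended values
#'
#' The heat-map representation of a chronic stream: one row per civil
#' day, one column per clock-time bin, each cell the central statistic of
#' that day's samples in that bin. Missing cells are `NA`, never
#' zero-filled.
#'
#' @param series A [band_power_series] (normally detrended).
#' @param bin_width Bin width in seconds (default 1800).
#' @param statistic `"median"` (default) or `"mean"`.
#' @return A `day_matrix`: `matrix` (days x bins), `day_labels`,
#'   `bin_centers`.
#' @export
day_matrix <- function(series, bin_width = 1800,
                       statistic = c("median", "mean")) {
  stopifnot(inherits(series, "band_power_series"))
  statistic <- match.arg(statistic)
  fun <- if (statistic == "median") median else mean
  n_bins <- as.integer(86400 / bin_width)
  clock <- clock_seconds(series)
  day <- local_dates(series)
  days <- unique(day)
  idx <- clock_bin(clock, bin_width)
  m <- tapply(series$values,
              list(factor(day, levels = days),
                   factor(idx, levels = 0:(n_bins - 1))),
              fun)
  m <- matrix(as.numeric(m), nrow = length(days), ncol = n_bins,
              dimnames = list(days, seconds_to_clock((0:(n_bins - 1) + 0.5) *
                                                       bin_width)))
  structure(
    list(matrix = m, day_labels = days,
         bin_centers = (0:(n_bins - 1) + 0.5) * bin_width),
    class = "day_matrix"
  )
}

#' @export
print.day_matrix <- function(x, ...) {
  cat(sprintf("<day_matrix> %d day(s) x %d bins; %d missing cell(s)\n",
              nrow(x$matrix), ncol(x$matrix), sum(is.na(x$matrix))))
  invisible(x)
}
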