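#' Read or construct a sleep diary
#'
#' A sleep diary holds one in-bed interval per date: `date` (the civil
#' date the interval starts on), `bed_time` and `rise_time` as local
#' `"HH:MM"` or `"HH:MM:SS"` clock times. When `rise_time` is not later
#' than `bed_time` the interval crosses midnight into the following date
#' (e.g. bed 23:00, rise 06:30); intervals must have positive duration.
#'
#' @param path CSV file with header `date,bed_time,rise_time`.
#' @return A `sleep_diary` data frame.
#' @seealso [generate_sleep_diary()], [in_bed_mask()]
#' @export
read_sleep_diary <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("date", "bed_time", "rise_time")
  if (!all(needed %in% names(df))) {
    stop("diary CSV must have columns date,bed_time,rise_time",
         call. = FALSE)
  }
  df$date <- as.Date(df$date)
  structure(df[, needed], class = c("sleep_diary", "data.frame"))
}

# In-bed intervals as POSIXct (start, end) in the series' timezone.
diary_intervals <- function(diary, tz) {
  bed <- clock_to_seconds(diary$bed_time)
  rise <- clock_to_seconds(diary$rise_time)
  day0 <- as.POSIXct(paste(diary$date, "00:00:00"), tz = tz)
  start <- day0 + bed
  end <- day0 + ifelse(rise > bed, rise, rise + 86400)
  if (any(end <= start)) {
    stop("diary contains a non-positive in-bed interval", call. = FALSE)
  }
  data.frame(date = diary$date, start = start, end = end)
}

#' In-bed mask for a chronic series
#'
#' Marks each sample as in-bed (`TRUE`), out-of-bed (`FALSE`) or
#' undefined (`NA`) according to a sleep diary. A sample is in-bed iff
#' its timestamp lies within any diary interval; samples on civil dates
#' the diary does not cover (neither as an interval's start date nor
#' reachable from the previous night's interval) are `NA` rather than
#' assumed out-of-bed.
#'
#' @param series A [band_power_series].
#' @param diary A `sleep_diary` (see [read_sleep_diary()]).
#' @return Logical vector, one element per sample, with `NA` for
#'   diary-uncovered days.
#' @export
in_bed_mask <- function(series, diary) {
  stopifnot(inherits(series, "band_power_series"))
  n <- length(series)
  if (nrow(diary) == 0L) return(rep(NA, n))
  tz <- series_tz(series)
  iv <- diary_intervals(diary, tz)
  ts <- as.numeric(series$timestamps)
  mask <- rep(NA, n)
  # a date is "covered" if the diary has an entry for it or the previous
  # day's interval extends into it
  dates <- as.Date(local_dates(series))
  covered <- dates %in% iv$date | (dates - 1) %in% iv$date
  mask[covered] <- FALSE
  for (i in seq_len(nrow(iv))) {
    inb <- ts >= as.numeric(iv$start[i]) & ts < as.numeric(iv$end[i])
    mask[inb] <- TRUE
  }
  mask
}

#' Align daily traces to a per-day clock event
#'
#' Re-indexes each civil day's samples by lag relative to that day's
#' event time (e.g. diary rise time, or first scheduled medication
#' intake), producing one trace per day on a common lag grid plus the
#' across-day mean trace. This is how wake-up or medication-locked power
#' transitions are summarized.
#'
#' @param series A [band_power_series].
#' @param event_times Either a single `"HH:MM"` clock time used every
#'   day, or a data frame with columns `date` and `time` (`"HH:MM"`).
#' @param lag_window Maximum absolute lag in seconds (default 6 h).
#' @return An `aligned_traces`: `lags` (s, negative = before the event),
#'   `traces` (days x lags matrix, `NA` where no sample), `mean_trace`,
#'   `day_labels`.
#' @export
align_to_daily_event <- function(series, event_times, lag_window = 6 * 3600) {
  stopifnot(inherits(series, "band_power_series"))
  tz <- series_tz(series)
  dates <- as.Date(unique(local_dates(series)))
  if (is.character(event_times) && length(event_times) == 1L) {
    ev <- data.frame(date = dates, time = event_times)
  } else {
    ev <- as.data.frame(event_times)
    stopifnot(all(c("date", "time") %in% names(ev)))
    ev$date <- as.Date(ev$date)
    ev <- ev[ev$date %in% dates, , drop = FALSE]
  }
  if (nrow(ev) == 0L) {
    stop("no event times fall inside the series span", call. = FALSE)
  }
  interval <- series$sample_interval
  lags <- seq(-lag_window, lag_window, by = interval)
  ts <- as.numeric(series$timestamps)
  traces <- matrix(NA_real_, nrow = nrow(ev), ncol = length(lags),
                   dimnames = list(as.character(ev$date), NULL))
  for (i in seq_len(nrow(ev))) {
    ev_abs <- as.numeric(as.POSIXct(paste(ev$date[i], "00:00:00"),
                                    tz = tz)) +
      clock_to_seconds(ev$time[i])
    lag_i <- ts - ev_abs
    sel <- which(lag_i >= min(lags) - interval / 2 &
                   lag_i <= max(lags) + interval / 2)
    if (!length(sel)) next
    pos <- round((lag_i[sel] - lags[1L]) / interval) + 1L
    ok <- pos >= 1L & pos <= length(lags)
    traces[i, pos[ok]] <- series$values[sel][ok]
  }
  mean_trace <- colMeans(traces, na.rm = TRUE)
  mean_trace[!is.finite(mean_trace)] <- NA_real_
  structure(
    list(lags = lags, traces = traces, mean_trace = mean_trace,
         day_labels = as.character(ev$date)),
    class = "aligned_traces"
  )
}

#' @export
print.aligned_traces <- function(x, ...) {
  cat(sprintf("<aligned_traces> %d day(s) x %d lag points (%+.1f..%+.1f h)\n",
              nrow(x$traces), length(x$lags),
              min(x$lags) / 3600, max(x$lags) / 3600))
  invisible(x)
}

#' Sleep/wake power contrast
#'
#' Mean power inside vs outside the diary in-bed intervals, and their
#' ratio. Samples on diary-uncovered days are excluded from both classes.
#'
#' @param series A [band_power_series].
#' @param diary A `sleep_diary`.
#' @return List with `mean_in_bed`, `mean_out_of_bed`, `ratio`
#'   (in/out), `n_in`, `n_out`.
#' @export
sleep_wake_contrast <- function(series, diary) {
  mask <- in_bed_mask(series, diary)
  if (all(is.na(mask))) {
    stop("diary covers none of the series dates", call. = FALSE)
  }
  v_in <- series$values[which(mask)]
  v_out <- series$values[which(!mask)]
  if (!length(v_in) || !length(v_out)) {
    stop("one of the in-bed/out-of-bed classes is empty", call. = FALSE)
  }
  list(mean_in_bed = mean(v_in), mean_out_of_bed = mean(v_out),
       ratio = mean(v_in) / mean(v_out),
       n_in = length(v_in), n_out = length(v_out))
}

#' Day/night value distributions and in-clinic comparison
#'
#' Collects the raw power values falling in the daytime (default
#' 08:00-20:00) and night-time (default 00:00-06:00) clock windows,
#' their log10 transforms, quartiles and range, and optionally locates a
#' single in-clinic measurement within the daytime distribution (its
#' percentile). A two-component-vs-one Gaussian mixture comparison by
#' BIC on the log10 daytime values flags bimodality, the signature of
#' clustered daytime movement/dyskinesia artifacts.
#'
#' @param series A [band_power_series] of raw (positive) power.
#' @param in_clinic_value Optional single in-clinic power value (uVp).
#' @param day_window,night_window Clock windows (`"HH:MM"` pairs).
#' @return A `day_night_summary`: per window the values, `log10_values`,
#'   `quartiles` (25/50/75), `range`; plus `in_clinic_value`,
#'   `in_clinic_percentile` (within daytime values; `NA` if not given),
#'   `daytime_bimodal` (logical), `bic_1`, `bic_2`.
#' @export
day_night_summary <- function(series, in_clinic_value = NULL,
                              day_window = c("08:00", "20:00"),
                              night_window = c("00:00", "06:00")) {
  stopifnot(inherits(series, "band_power_series"))
  if (any(series$values <= 0)) {
    stop("day/night summary needs strictly positive power values",
         call. = FALSE)
  }
  clock <- clock_seconds(series)
  pick <- function(win) {
    w <- clock_to_seconds(win)
    if (w[1] < w[2]) series$values[clock >= w[1] & clock < w[2]]
    else series$values[clock >= w[1] | clock < w[2]]
  }
  day_v <- pick(day_window)
  night_v <- pick(night_window)
  if (!length(day_v) || !length(night_v)) {
    stop("empty day or night window", call. = FALSE)
  }
  summarize <- function(v) {
    list(values = v, log10_values = log10(v),
         quartiles = quantile(v, c(0.25, 0.5, 0.75), names = FALSE),
         range = range(v))
  }
  pctl <- NA_real_
  if (!is.null(in_clinic_value)) {
    pctl <- 100 * mean(day_v <= in_clinic_value)
  }
  lx <- log10(day_v)
  bic <- mclust::mclustBIC(lx, G = 1:2, modelNames = "V", verbose = FALSE)
  bic1 <- as.numeric(bic["1", "V"])
  bic2 <- as.numeric(bic["2", "V"])
  if (!is.finite(bic2)) bic2 <- -Inf
  structure(
    list(day = summarize(day_v), night = summarize(night_v),
         day_window = day_window, night_window = night_window,
         in_clinic_value = in_clinic_value,
         in_clinic_percentile = pctl,
         daytime_bimodal = bic2 > bic1, bic_1 = bic1, bic_2 = bic2),
    class = "day_night_summary"
  )
}

#' @export
print.day_night_summary <- function(x, ...) {
  cat(sprintf(
    "<day_night_summary> day (%s-%s) median %.3g | night (%s-%s) median %.3g\n",
    x$day_window[1], x$day_window[2], x$day$quartiles[2],
    x$night_window[1], x$night_window[2], x$night$quartiles[2]))
  if (!is.null(x$in_clinic_value)) {
    cat(sprintf("  in-clinic %.3g uVp at daytime percentile %.1f\n",
                x$in_clinic_value, x$in_clinic_percentile))
  }
  cat(sprintf("  daytime log10 distribution bimodal: %s\n",
              x$daytime_bimodal))
  invisible(x)
}
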