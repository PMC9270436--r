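# Welch power spectral density estimate. One-sided density in units of
# x^2 per Hz: averaging modified periodograms of Hann-tapered,
# linearly-detrended, 50%-overlapping segments. Written here because no
# installed package provides a Welch estimator; normalized so that
# sum(psd) * df approximates the input variance (Parseval).
welch_psd <- function(x, fs, nperseg, overlap = 0.5,
                      detrend_segments = TRUE) {
  n <- length(x)
  nperseg <- as.integer(min(nperseg, n))
  if (nperseg < 8L) stop("segment too short for Welch estimate",
                         call. = FALSE)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1))  # Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nperseg %/% 2L
  acc <- numeric(nfreq + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    if (detrend_segments) {
      t_ix <- seq_along(seg)
      seg <- seg - (stats::lm.fit(cbind(1, t_ix), seg)$fitted.values)
    }
    X <- fft(seg * w)[1:(nfreq + 1L)]
    p <- (Mod(X)^2) * scale
    # double everything except DC (and Nyquist when nperseg is even)
    dbl <- rep(2, nfreq + 1L)
    dbl[1L] <- 1
    if (nperseg %% 2L == 0L) dbl[nfreq + 1L] <- 1
    acc <- acc + p * dbl
  }
  psd <- acc / length(starts)
  freq <- (0:nfreq) * fs / nperseg
  list(freq = freq, psd = psd, n_segments = length(starts),
       nperseg = nperseg)
}

# Put a series on its regular nominal grid; linearly interpolate gaps up
# to max_gap seconds, leave longer gaps as NA. Returns the grid values and
# the runs of contiguous (non-NA) samples.
regularize_series <- function(series, max_gap = 7200) {
  interval <- series$sample_interval
  t0 <- as.numeric(series$timestamps[1L])
  pos <- round((as.numeric(series$timestamps) - t0) / interval)
  n <- max(pos) + 1L
  grid <- rep(NA_real_, n)
  grid[pos + 1L] <- series$values
  if (anyNA(grid)) {
    filled <- approx(which(!is.na(grid)), grid[!is.na(grid)],
                     xout = seq_len(n))$y
    # only fill gaps shorter than max_gap
    r <- rle(is.na(grid))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (r$lengths[k] * interval <= max_gap) {
        grid[starts[k]:ends[k]] <- filled[starts[k]:ends[k]]
      }
    }
  }
  list(values = grid, interval = interval, t0 = t0)
}

#' Welch periodogram of a chronic band-power series
#'
#' Estimates the power spectrum of the (typically detrended) chronic
#' stream as a function of period, to test for 24-h periodicity. The
#' series is first placed on its regular nominal sampling grid (gaps up
#' to `max_gap` are linearly interpolated; longer gaps split the record
#' and each contiguous chunk contributes its own Welch segments). The
#' spectral estimate uses Hann windows of `segment_days` days at 50%
#' overlap with per-segment linear detrending; a 4-day window places the
#' 24-h period exactly on a frequency bin. The dominant period is the
#' argmax of spectral power over periods between `min_period_h` hours and
#' half the record length.
#'
#' @param series A [band_power_series] spanning at least 2 days.
#' @param segment_days Welch window length in days (default 4).
#' @param max_gap Longest gap (s) to interpolate across (default 7200).
#' @param min_period_h Shortest period searched, hours (default 2).
#' @return A `periodogram_result`: `period_hours`, `power` (normalized to
#'   unit total within the searched range), `dominant_period_h`,
#'   `freq_cpd` (cycles/day).
#' @export
#'
#' @examples
#' cfg <- diurnal_sim_config(n_days = 8, noise_cv = 0.1, seed = 2)
#' s <- detrend_daily(generate_diurnal_series(cfg))
#' periodogram(s)$dominant_period_h  # 24
periodogram <- function(series, segment_days = 4, max_gap = 7200,
                        min_period_h = 2) {
  stopifnot(inherits(series, "band_power_series"))
  span_s <- diff(range(as.numeric(series$timestamps)))
  if (span_s < 2 * 86400) {
    stop("record must span at least 2 days", call. = FALSE)
  }
  reg <- regularize_series(series, max_gap = max_gap)
  fs <- 1 / reg$interval                      # Hz
  nperseg <- as.integer(segment_days * 86400 / reg$interval)
  x <- reg$values
  # long gaps split the record into chunks analysed separately
  r <- rle(!is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  chunks <- lapply(which(r$values), function(k) x[starts[k]:ends[k]])
  chunks <- chunks[vapply(chunks, length, 1L) >= 16L]
  if (!length(chunks)) stop("no usable data after gap splitting",
                            call. = FALSE)
  nperseg <- min(nperseg, max(vapply(chunks, length, 1L)))
  acc <- NULL; nseg <- 0L
  for (ch in chunks) {
    if (length(ch) < nperseg) next
    w <- welch_psd(ch, fs, nperseg)
    if (is.null(acc)) acc <- w$psd * w$n_segments else
      acc <- acc + w$psd * w$n_segments
    nseg <- nseg + w$n_segments
  }
  psd <- acc / nseg
  freq <- (0:(nperseg %/% 2L)) * fs / nperseg
  keep <- freq > 0
  period_h <- 1 / freq[keep] / 3600
  power <- psd[keep]
  in_range <- period_h >= min_period_h & period_h <= span_s / 3600 / 2
  if (!any(in_range)) stop("no periods inside the searched range",
                           call. = FALSE)
  power_n <- power / sum(power[in_range])
  dom <- period_h[in_range][which.max(power[in_range])]
  structure(
    list(period_hours = period_h, power = power_n,
         freq_cpd = freq[keep] * 86400,
         dominant_period_h = dom, searched = in_range,
         segment_days = segment_days),
    class = "periodogram_result"
  )
}

#' @export
print.periodogram_result <- function(x, ...) {
  cat(sprintf(
    "<periodogram_result> dominant period %.2f h (%d periods searched)\n",
    x$dominant_period_h, sum(x$searched)))
  invisible(x)
}
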