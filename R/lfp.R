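#' Zero-phase band-pass filter for raw LFP
#'
#' 4th-order Butterworth band-pass (default 4-98 Hz, the preprocessing
#' applied before in-clinic band-power estimation) applied
#' forward-backward with `signal::filtfilt()` for zero phase shift. DC
#' is removed by the high-pass corner.
#'
#' @param stream An [lfp_stream()].
#' @param hp High-pass corner (Hz, default 4).
#' @param lp Low-pass corner (Hz, default 98); must be below Nyquist.
#' @param order Butterworth order per corner (default 4).
#' @return The filtered [lfp_stream()].
#' @export
filter_lfp <- function(stream, hp = 4, lp = 98, order = 4) {
  stopifnot(inherits(stream, "lfp_stream"))
  nyq <- stream$sample_rate / 2
  if (lp >= nyq) stop("low-pass corner must be below Nyquist (",
                      nyq, " Hz)", call. = FALSE)
  if (hp <= 0 || hp >= lp) stop("need 0 < hp < lp", call. = FALSE)
  bf <- signal::butter(order, c(hp, lp) / nyq, type = "pass")
  stream$samples <- as.numeric(signal::filtfilt(bf, stream$samples))
  stream
}

#' Welch power spectrum of an LFP stream
#'
#' One-sided power spectral density (uV^2/Hz) by Welch's method: Hann
#' windows with 50% overlap and per-segment linear detrending. The
#' estimate is Parseval-consistent: summing the density times the
#' frequency step approximates the signal variance.
#'
#' @param stream An [lfp_stream()].
#' @param nperseg Segment length in samples (default 1 s of data, at
#'   least 256).
#' @return List with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_spectrum <- function(stream, nperseg = NULL) {
  stopifnot(inherits(stream, "lfp_stream"))
  fs <- stream$sample_rate
  if (is.null(nperseg)) nperseg <- max(256L, as.integer(fs))
  if (length(stream$samples) < 2L * nperseg) {
    stop("stream too short: need at least 2 Welch windows", call. = FALSE)
  }
  w <- welch_psd(stream$samples, fs, nperseg)
  list(freq = w$freq, psd = w$psd)
}

#' Global Morlet wavelet spectrum
#'
#' Time-averaged wavelet power of a segment: a continuous Morlet
#' transform (center-frequency parameter 6) over log-spaced frequencies
#' (default 4-98 Hz), with the power at each frequency averaged across
#' the segment. Unlike the Welch estimate this localizes transient
#' broadband events in frequency without assuming stationarity; units
#' are arbitrary.
#'
#' @param stream An [lfp_stream()] segment of at least 1 s.
#' @param freqs Frequencies (Hz) at which to evaluate; default 60
#'   log-spaced values in 4-98 Hz.
#' @param omega0 Morlet center-frequency parameter (default 6).
#' @return List with `freq` (Hz) and `power` (arbitrary units).
#' @export
global_wavelet_spectrum <- function(stream, freqs = NULL, omega0 = 6) {
  stopifnot(inherits(stream, "lfp_stream"))
  fs <- stream$sample_rate
  x <- stream$samples
  n <- length(x)
  if (n < fs) stop("segment must be at least 1 s long", call. = FALSE)
  if (is.null(freqs)) freqs <- exp(seq(log(4), log(98), length.out = 60))
  x <- x - mean(x)
  xf <- fft(x)
  # angular frequencies of the DFT grid
  k <- 0:(n - 1)
  wk <- 2 * pi * ifelse(k <= n / 2, k, k - n) * fs / n
  fourier_factor <- (4 * pi) / (omega0 + sqrt(2 + omega0^2))
  power <- vapply(freqs, function(f) {
    scale <- 1 / (f * fourier_factor)
    # Morlet daughter in the frequency domain (analytic: positive freqs)
    psi <- sqrt(2 * pi * scale * fs) * pi^(-0.25) *
      exp(-((scale * wk - omega0)^2) / 2) * (wk > 0)
    wt <- fft(xf * psi, inverse = TRUE) / n
    mean(Mod(wt)^2)
  }, numeric(1))
  list(freq = freqs, power = power)
}

#' Band power of an LFP segment (uVp-equivalent)
#'
#' Power in a frequency band, expressed on a peak-to-peak-equivalent
#' microvolt scale: the segment is zero-phase band-pass filtered to the
#' band and the value returned is 2*sqrt(2) times the RMS of the
#' filtered signal, so a pure in-band sinusoid of amplitude A yields 2A.
#' This documented convention mimics the peak-amplitude-style band-power
#' readout of chronic sensing devices; absolute values are not
#' comparable to any particular device, relative (%%-of-rest) values
#' are the supported quantity.
#'
#' @param stream An [lfp_stream()] (or a filtered segment of one).
#' @param band List or vector with `low` and `high` (Hz).
#' @param order Butterworth order (default 4).
#' @return Scalar band power, uVp-equivalent (non-negative).
#' @export
band_power <- function(stream, band, order = 4) {
  stopifnot(inherits(stream, "lfp_stream"))
  if (!length(stream$samples)) stop("empty segment", call. = FALSE)
  lo <- band$low %||% band[[1]]
  hi <- band$high %||% band[[2]]
  nyq <- stream$sample_rate / 2
  stopifnot(0 < lo, lo < hi, hi <= 98, hi < nyq)
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  y <- as.numeric(signal::filtfilt(bf, stream$samples))
  2 * sqrt(2) * sqrt(mean(y^2))
}

#' Band definition around a subject-specific peak
#'
#' Convenience constructor for the two chronic-sensing bands: a 5 Hz
#' window centered on the subject's beta peak, and the fixed 4-8 Hz
#' theta band.
#'
#' @param center_hz Center frequency (Hz).
#' @param width_hz Full width (Hz, default 5).
#' @param name Band name.
#' @return List with `name`, `low`, `high`.
#' @export
band_around_peak <- function(center_hz, width_hz = 5, name = "beta") {
  low <- center_hz - width_hz / 2
  high <- center_hz + width_hz / 2
  stopifnot(0 < low, high <= 98)
  list(name = name, low = low, high = high)
}

#' Movement-epoch band-power table
#'
#' For each annotated movement label, the mean beta and theta band power
#' across that label's epochs (equal weight per epoch), both absolute
#' (uVp-equivalent) and relative to the rest epochs (rest = 100%). This
#' quantifies how much everyday movements inflate the band-power
#' readout; broadband movement artifacts typically inflate theta at
#' least as much as beta, and both above rest.
#'
#' @param stream An [lfp_stream()]; it is band-pass filtered 4-98 Hz
#'   with [filter_lfp()] before band-power estimation.
#' @param annotations Data frame with columns `label`, `start_s`,
#'   `end_s` (seconds from stream start). A `"rest"` label must be
#'   present; epochs must lie within the stream span.
#' @param beta_band,theta_band Band definitions (see
#'   [band_around_peak()]); defaults: 5 Hz around 20 Hz, and 4-8 Hz.
#' @return A `movement_power_table` data frame with one row per label:
#'   `label`, `n_epochs`, `beta_uvp`, `beta_rel_pct`, `theta_uvp`,
#'   `theta_rel_pct`. The rest row's relative values are exactly 100.
#' @export
movement_power_table <- function(stream, annotations,
                                 beta_band = band_around_peak(20),
                                 theta_band = list(name = "theta",
                                                   low = 4, high = 8)) {
  stopifnot(inherits(stream, "lfp_stream"))
  ann <- as.data.frame(annotations)
  stopifnot(all(c("label", "start_s", "end_s") %in% names(ann)))
  if (!"rest" %in% ann$label) {
    stop("annotations must contain a 'rest' epoch", call. = FALSE)
  }
  dur <- length(stream$samples) / stream$sample_rate
  if (any(ann$start_s < 0 | ann$end_s > dur)) {
    stop("annotation epoch outside the stream span", call. = FALSE)
  }
  filtered <- filter_lfp(stream)
  fs <- stream$sample_rate
  epoch_power <- function(row, band) {
    i0 <- max(1L, floor(row$start_s * fs) + 1L)
    i1 <- min(length(filtered$samples), ceiling(row$end_s * fs))
    seg <- lfp_stream(filtered$samples[i0:i1], sample_rate = fs)
    band_power(seg, band)
  }
  labels <- unique(ann$label)
  rows <- lapply(labels, function(lab) {
    ep <- ann[ann$label == lab, , drop = FALSE]
    b <- vapply(seq_len(nrow(ep)),
                function(i) epoch_power(ep[i, ], beta_band), numeric(1))
    th <- vapply(seq_len(nrow(ep)),
                 function(i) epoch_power(ep[i, ], theta_band), numeric(1))
    data.frame(label = lab, n_epochs = nrow(ep),
               beta_uvp = mean(b), theta_uvp = mean(th))
  })
  tab <- do.call(rbind, rows)
  rest <- tab[tab$label == "rest", ]
  tab$beta_rel_pct <- 100 * tab$beta_uvp / rest$beta_uvp
  tab$theta_rel_pct <- 100 * tab$theta_uvp / rest$theta_uvp
  # the rest row is 100% by definition, not merely to float tolerance
  tab$beta_rel_pct[tab$label == "rest"] <- 100
  tab$theta_rel_pct[tab$label == "rest"] <- 100
  tab <- tab[, c("label", "n_epochs", "beta_uvp", "beta_rel_pct",
                 "theta_uvp", "theta_rel_pct")]
  class(tab) <- c("movement_power_table", "data.frame")
  tab
}

#' Read a raw LFP stream from CSV
#'
#' Single-channel CSV with header `time_s,uv`: sample times in seconds
#' (must be uniformly spaced) and voltages in microvolts.
#'
#' @param path CSV file.
#' @return An [lfp_stream()].
#' @export
read_lfp_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "uv") %in% names(df))) {
    stop("LFP CSV must have columns time_s,uv", call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop("LFP CSV samples are not uniformly spaced", call. = FALSE)
  }
  lfp_stream(df$uv, sample_rate = 1 / stats::median(dt))
}

#' Read movement annotations from CSV
#'
#' CSV with header `label,start_s,end_s`.
#'
#' @param path CSV file.
#' @return Data frame of annotations.
#' @export
read_annotations_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "start_s", "end_s") %in% names(df))) {
    stop("annotations CSV must have columns label,start_s,end_s",
         call. = FALSE)
  }
  df
}
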