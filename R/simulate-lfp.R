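#' Raw LFP stream
#'
#' A short raw local field potential recording (microvolts) at a fixed
#' sampling rate, as streamed from the implanted device during in-clinic
#' sessions (250 Hz on current hardware).
#'
#' @param samples Numeric vector of voltages (uV); must be finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param start_time `POSIXct` start of the recording (optional).
#' @param channel Channel label.
#' @return An `lfp_stream` object.
#' @export
lfp_stream <- function(samples, sample_rate = 250,
                       start_time = as.POSIXct("2021-06-01", tz = "UTC"),
                       channel = "STN") {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  structure(list(samples = samples, sample_rate = sample_rate,
                 start_time = start_time, channel = channel),
            class = "lfp_stream")
}

#' @export
print.lfp_stream <- function(x, ...) {
  cat(sprintf("<lfp_stream> %s: %d samples @ %g Hz (%.1f s)\n",
              x$channel, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Configuration for a synthetic raw LFP stream
#'
#' The simulated LFP is a band-limited oscillation at the subject's beta
#' peak frequency riding on 1/f ("aperiodic") background noise, with
#' optional labelled movement-artifact epochs during which additional
#' broadband (1/f-shaped) noise of a given amplitude is injected —
#' mimicking the broadband transients that everyday movements impose on
#' device recordings.
#'
#' @param duration Recording length in seconds (> 0).
#' @param sample_rate Hz (default 250); must exceed 2 x 98 Hz.
#' @param beta_peak_freq Oscillation frequency in Hz (default 20).
#' @param beta_amp Oscillation amplitude in uV (0 disables it).
#' @param aperiodic_exponent Exponent of the 1/f background (power
#'   spectral density proportional to f^-exponent; default 1).
#' @param noise_amp RMS amplitude (uV) of the 1/f background.
#' @param artifact_epochs Data frame with columns `label`, `start_s`,
#'   `end_s`, `amplitude` (RMS uV of injected broadband noise); epochs
#'   with the same label must not overlap.
#' @param seed Integer seed.
#' @return An `lfp_sim_config` list.
#' @export
lfp_sim_config <- function(duration,
                           sample_rate = 250,
                           beta_peak_freq = 20,
                           beta_amp = 5,
                           aperiodic_exponent = 1,
                           noise_amp = 2,
                           artifact_epochs = NULL,
                           seed = 1L) {
  if (duration <= 0) stop("invalid `duration`: must be > 0", call. = FALSE)
  if (sample_rate <= 2 * 98) {
    stop("invalid `sample_rate`: must exceed 196 Hz (2 x 98 Hz)",
         call. = FALSE)
  }
  if (!is.null(artifact_epochs)) {
    stopifnot(all(c("label", "start_s", "end_s", "amplitude") %in%
                    names(artifact_epochs)))
    if (any(artifact_epochs$end_s <= artifact_epochs$start_s)) {
      stop("artifact epochs must have end_s > start_s", call. = FALSE)
    }
    for (lab in unique(artifact_epochs$label)) {
      ep <- artifact_epochs[artifact_epochs$label == lab, , drop = FALSE]
      ep <- ep[order(ep$start_s), , drop = FALSE]
      if (nrow(ep) > 1L &&
          any(ep$start_s[-1L] < ep$end_s[-nrow(ep)])) {
        stop("overlapping artifact epochs with identical label '", lab, "'",
             call. = FALSE)
      }
    }
  }
  structure(
    list(duration = duration, sample_rate = sample_rate,
         beta_peak_freq = beta_peak_freq, beta_amp = beta_amp,
         aperiodic_exponent = aperiodic_exponent, noise_amp = noise_amp,
         artifact_epochs = artifact_epochs, seed = seed),
    class = "lfp_sim_config"
  )
}

# Gaussian noise with power spectral density ~ f^-exponent, unit RMS,
# synthesized by FFT spectral shaping. Deterministic given the RNG state.
aperiodic_noise <- function(n, exponent) {
  x <- rnorm(n)
  if (exponent == 0) return(x / sd(x))
  xf <- fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)  # symmetric frequency index; f = 0 at DC
  scale <- ifelse(f == 0, 0, f^(-exponent / 2))
  y <- Re(fft(xf * scale, inverse = TRUE)) / n
  y / sd(y)
}

#' Generate a synthetic raw LFP stream with movement annotations
#'
#' @param config An [lfp_sim_config()].
#' @return A list with elements `stream` (an [lfp_stream()]) and
#'   `annotations` (the config's artifact epochs as a data frame with
#'   columns `label`, `start_s`, `end_s`, or an empty frame).
#' @export
#'
#' @examples
#' cfg <- lfp_sim_config(duration = 10, beta_amp = 5, seed = 3)
#' generate_lfp_stream(cfg)$stream
generate_lfp_stream <- function(config) {
  stopifnot(inherits(config, "lfp_sim_config"))
  fs <- config$sample_rate
  n <- round(config$duration * fs)
  t <- (0:(n - 1)) / fs
  x <- with_seed(config$seed, {
    phase <- runif(1, 0, 2 * pi)
    sig <- config$beta_amp *
      sin(2 * pi * config$beta_peak_freq * t + phase)
    if (config$noise_amp > 0) {
      sig <- sig + config$noise_amp *
        aperiodic_noise(n, config$aperiodic_exponent)
    }
    ep <- config$artifact_epochs
    if (!is.null(ep) && nrow(ep)) {
      for (i in seq_len(nrow(ep))) {
        idx <- which(t >= ep$start_s[i] & t < ep$end_s[i])
        if (length(idx) > 1L) {
          sig[idx] <- sig[idx] + ep$amplitude[i] *
            aperiodic_noise(length(idx), config$aperiodic_exponent)
        }
      }
    }
    sig
  })
  ann <- if (is.null(config$artifact_epochs)) {
    data.frame(label = character(0), start_s = numeric(0),
               end_s = numeric(0))
  } else {
    config$artifact_epochs[, c("label", "start_s", "end_s"), drop = FALSE]
  }
  list(stream = lfp_stream(x, sample_rate = fs), annotations = ann)
}
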