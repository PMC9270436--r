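#' Read a chronic band-power series from disk
#'
#' Two plain-text formats are supported. `"csv"` uses the package's standard
#' schema with header
#' `timestamp_utc,value_uvp,subject,hemisphere,band_center_hz,band_width_hz`
#' and ISO-8601 UTC timestamps, one record per sample. `"device_json"` is a
#' simplified device-export layout: a JSON object with a `metadata` block
#' (`subject`, `hemisphere`, `band_center_hz`, `band_width_hz`, `band_name`,
#' `sample_interval_s`) and a `samples` array of `{ts, value}` records.
#'
#' Timestamps must be strictly increasing and values non-negative; files
#' violating either are rejected with the offending record identified.
#'
#' @param path File to read.
#' @param format `"csv"` or `"device_json"`.
#' @return A [band_power_series] with UTC timestamps.
#' @seealso [write_series()], [to_local_time()]
#' @export
read_series <- function(path, format = c("csv", "device_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    needed <- c("timestamp_utc", "value_uvp", "subject", "hemisphere",
                "band_center_hz", "band_width_hz")
    missing <- setdiff(needed, names(df))
    if (length(missing)) {
      stop("CSV schema violation in ", path, ": missing column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    ts <- parse_iso8601(df$timestamp_utc)
    if (anyNA(ts)) {
      bad <- which(is.na(ts))[1L]
      stop(sprintf("unparseable timestamp at data row %d: '%s'",
                   bad, df$timestamp_utc[bad]), call. = FALSE)
    }
    if (any(df$value_uvp < 0)) {
      bad <- which(df$value_uvp < 0)[1L]
      stop(sprintf("negative power at data row %d", bad), call. = FALSE)
    }
    band_name <- if ("band_name" %in% names(df)) df$band_name[1L] else "beta"
    check_monotone(ts)
    band_power_series(
      ts, df$value_uvp,
      subject_id = as.character(df$subject[1L] %||% "unknown"),
      hemisphere = as.character(df$hemisphere[1L]),
      band = list(center_hz = df$band_center_hz[1L],
                  width_hz = df$band_width_hz[1L], name = band_name)
    )
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(obj$samples) || is.null(obj$metadata)) {
      stop("device_json schema violation in ", path,
           ": need 'metadata' and 'samples'", call. = FALSE)
    }
    md <- obj$metadata
    ts <- parse_iso8601(obj$samples$ts)
    if (anyNA(ts)) stop("unparseable timestamp in 'samples'", call. = FALSE)
    if (any(obj$samples$value < 0)) {
      stop("negative power in 'samples'", call. = FALSE)
    }
    check_monotone(ts)
    band_power_series(
      ts, obj$samples$value,
      subject_id = md$subject %||% "unknown",
      hemisphere = md$hemisphere %||% NA_character_,
      band = list(center_hz = md$band_center_hz %||% NA_real_,
                  width_hz = md$band_width_hz %||% NA_real_,
                  name = md$band_name %||% "beta"),
      sample_interval = md$sample_interval_s %||% 600
    )
  }
}

check_monotone <- function(ts) {
  if (length(ts) > 1L && any(diff(as.numeric(ts)) <= 0)) {
    bad <- which(diff(as.numeric(ts)) <= 0)[1L] + 1L
    stop(sprintf("timestamps not strictly increasing at record %d", bad),
         call. = FALSE)
  }
  invisible(ts)
}

parse_iso8601 <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS%z",
                                   "%Y-%m-%dT%H:%M:%OSZ",
                                   "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS"),
                    optional = TRUE)
  attr(out, "tzone") <- "UTC"
  out
}

#' Write a chronic band-power series to disk
#'
#' Writes the standard CSV schema or the simplified device-export JSON (see
#' [read_series()]). Timestamps are serialized as ISO-8601 UTC with full
#' seconds and values at full double precision, so `write_series()` followed
#' by `read_series()` round-trips losslessly. An empty series produces a
#' header-only CSV.
#'
#' @param series A [band_power_series].
#' @param path Output file.
#' @param format `"csv"` or `"device_json"`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, format = c("csv", "device_json")) {
  format <- match.arg(format)
  stopifnot(inherits(series, "band_power_series"))
  ts_utc <- format(series$timestamps, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (format == "csv") {
    df <- data.frame(
      timestamp_utc = ts_utc,
      value_uvp = sprintf("%.17g", series$values),
      subject = rep(series$subject_id, length(ts_utc)),
      hemisphere = rep(series$hemisphere, length(ts_utc)),
      band_center_hz = rep(series$band$center_hz, length(ts_utc)),
      band_width_hz = rep(series$band$width_hz, length(ts_utc)),
      band_name = rep(series$band$name, length(ts_utc)),
      stringsAsFactors = FALSE
    )
    if (length(ts_utc) == 0L) df <- df[0L, , drop = FALSE]
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(
      metadata = list(subject = series$subject_id,
                      hemisphere = series$hemisphere,
                      band_center_hz = series$band$center_hz,
                      band_width_hz = series$band$width_hz,
                      band_name = series$band$name,
                      sample_interval_s = series$sample_interval),
      samples = data.frame(ts = ts_utc, value = series$values)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Re-label timestamps in a local civil timezone
#'
#' Sensing devices log timestamps in UTC; all day-based analyses (daily
#' detrending, clock-time binning, day/night windows) operate on local civil
#' time. This relabels the instants in an IANA zone without changing them,
#' so daylight-saving transitions are handled by the zone database: a
#' transition day simply contains 23 or 25 hours of samples.
#'
#' @param series A [band_power_series].
#' @param tz_name IANA zone name, e.g. `"Europe/Berlin"`.
#' @return The series with timestamps labelled in `tz_name`.
#' @export
to_local_time <- function(series, tz_name) {
  stopifnot(inherits(series, "band_power_series"))
  if (!tz_name %in% OlsonNames()) {
    stop("unknown timezone: ", tz_name, call. = FALSE)
  }
  attr(series$timestamps, "tzone") <- tz_name
  series
}
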