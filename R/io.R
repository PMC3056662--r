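# Plain-text readers/writers for the tabular interchange formats used by the
# pipeline, plus minimal RIFF/WAVE PCM-16 I/O for calibrated tag audio.

read_schema_csv <- function(path, required) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  assert_cols(df, required, what = path)
  df
}

#' Read and write click-train event tables
#'
#' Events are one row per detected click train on one hydrophone, with
#' columns `phone_id`, `start_s`, `end_s`, `n_clicks`, `species`.
#'
#' @param path Path to a CSV file.
#' @param events Tibble of click-train events.
#' @return `read_click_events()` returns a tibble; the writers return the
#'   input invisibly.
#' @export
read_click_events <- function(path) {
  read_schema_csv(path, c("phone_id", "start_s", "end_s", "n_clicks", "species"))
}

#' @rdname read_click_events
#' @export
write_click_events <- function(events, path) {
  assert_cols(events, c("phone_id", "start_s", "end_s", "n_clicks", "species"))
  utils::write.csv(events, path, row.names = FALSE)
  invisible(events)
}

#' Read and write hydrophone array geometry
#'
#' Columns: `phone_id`, `x_m`, `y_m`, `depth_m` in a local planar frame.
#'
#' @param path Path to a CSV file.
#' @param array Tibble of hydrophone positions.
#' @return A tibble (reader) or the input, invisibly (writer).
#' @export
read_array <- function(path) {
  read_schema_csv(path, c("phone_id", "x_m", "y_m", "depth_m"))
}

#' @rdname read_array
#' @export
write_array <- function(array, path) {
  assert_cols(array, c("phone_id", "x_m", "y_m", "depth_m"))
  utils::write.csv(array, path, row.names = FALSE)
  invisible(array)
}

#' Read and write group clicking period tables
#'
#' The `phones` list-column is collapsed to a `;`-separated string on disk.
#'
#' @param path Path to a CSV file.
#' @param gcps Tibble of GCPs as returned by [detect_gcps()].
#' @return A tibble (reader) or the input, invisibly (writer).
#' @export
read_gcps <- function(path) {
  df <- read_schema_csv(path, c("gcp_id", "start_s", "end_s", "phones", "on_edge", "phase"))
  df$phones <- strsplit(as.character(df$phones), ";", fixed = TRUE)
  df$on_edge <- as.logical(df$on_edge)
  df
}

#' @rdname read_gcps
#' @export
write_gcps <- function(gcps, path) {
  assert_cols(gcps, c("gcp_id", "start_s", "end_s", "phones", "on_edge", "phase"))
  out <- gcps
  out$phones <- vapply(gcps$phones, paste, character(1), collapse = ";")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(gcps)
}

#' Read and write tag depth profiles and acoustic audit tables
#'
#' Depth profiles have columns `t_s`, `depth_m` (positive down); audits have
#' `t_s`, `event` with event one of `click_start`, `click_end`, `buzz`.
#'
#' @param path Path to a CSV file.
#' @param profile,audit Tibbles with the schemas above.
#' @return A tibble (readers) or the input, invisibly (writers).
#' @export
read_depth_profile <- function(path) read_schema_csv(path, c("t_s", "depth_m"))

#' @rdname read_depth_profile
#' @export
write_depth_profile <- function(profile, path) {
  assert_cols(profile, c("t_s", "depth_m"))
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(profile)
}

#' @rdname read_depth_profile
#' @export
read_audit <- function(path) {
  df <- read_schema_csv(path, c("t_s", "event"))
  bad <- setdiff(unique(df$event), c("click_start", "click_end", "buzz"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown audit event kind(s): %s.", paste(bad, collapse = ", ")))
  }
  df
}

#' @rdname read_depth_profile
#' @export
write_audit <- function(audit, path) {
  assert_cols(audit, c("t_s", "event"))
  utils::write.csv(audit, path, row.names = FALSE)
  invisible(audit)
}

#' Read and write satellite location fixes
#'
#' Columns on disk: `time_iso` (ISO-8601 UTC), `lat`, `lon`. In memory the
#' time is a POSIXct `time` column.
#'
#' @param path Path to a CSV file.
#' @param fixes Tibble with `time`, `lat`, `lon` (and optionally `retained`).
#' @return A tibble (reader) or the input, invisibly (writer).
#' @export
read_fixes <- function(path) {
  df <- read_schema_csv(path, c("time_iso", "lat", "lon"))
  tibble(
    time = as.POSIXct(df$time_iso, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S"),
    lat = df$lat,
    lon = df$lon
  )
}

#' @rdname read_fixes
#' @export
write_fixes <- function(fixes, path) {
  assert_cols(fixes, c("time", "lat", "lon"))
  out <- data.frame(
    time_iso = format(fixes$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lat = fixes$lat,
    lon = fixes$lon
  )
  if ("retained" %in% names(fixes)) out$retained <- fixes$retained
  utils::write.csv(out, path, row.names = FALSE)
  invisible(fixes)
}

#' Minimal WAV PCM-16 input/output for calibrated pressure records
#'
#' Reads or writes a single-channel 16-bit PCM RIFF/WAVE file. The tag
#' sensitivity `counts_per_upa` converts between integer sample counts and
#' calibrated pressure in micropascal, so `read_wav()` returns a
#' [pressure_series()] in physical units. Values that would clip the 16-bit
#' range on write raise an error rather than clipping silently.
#'
#' @param path File path.
#' @param counts_per_upa Sensitivity: integer counts per micropascal.
#' @param series A [pressure_series()].
#' @return `read_wav()` returns a [pressure_series()]; `write_wav()` returns
#'   `series` invisibly.
#' @export
read_wav <- function(path, counts_per_upa) {
  assert_scalar_number(counts_per_upa, "counts_per_upa", positive = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("Not a RIFF file.")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("Not a WAVE file.")
  sample_rate <- NULL
  bits <- NULL
  n_channels <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) abort("Only PCM WAV is supported.")
      n_channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      if (is.null(bits)) abort("WAV data chunk before fmt chunk.")
      if (bits != 16L) abort("Only 16-bit PCM WAV is supported.")
      samples <- readBin(con, "integer", sz / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  if (is.null(samples)) abort("No data chunk found in WAV file.")
  if (!is.null(n_channels) && n_channels != 1L) {
    abort("Only single-channel WAV is supported.")
  }
  pressure_series(samples / counts_per_upa, sample_rate)
}

#' @rdname read_wav
#' @export
write_wav <- function(series, path, counts_per_upa) {
  if (!inherits(series, "pressure_series")) {
    abort("`series` must be a pressure_series.")
  }
  assert_scalar_number(counts_per_upa, "counts_per_upa", positive = TRUE)
  counts <- round(series$samples * counts_per_upa)
  if (any(abs(counts) > 32767)) {
    abort("Samples exceed the 16-bit PCM range at this sensitivity; lower `counts_per_upa`.")
  }
  n <- length(counts)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(series$sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(series$sample_rate_hz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(as.integer(counts), con, size = 2, endian = "little")
  invisible(series)
}
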