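#' Calibrated acoustic pressure series
#'
#' Container for a regularly sampled, calibrated pressure record such as the
#' output of an acoustic recording tag after applying the hydrophone
#' sensitivity. Samples are in micropascal.
#'
#' @param samples Numeric vector of instantaneous pressure in micropascal.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param start_time_s Time of the first sample in seconds.
#' @return An object of class `pressure_series`.
#' @examples
#' fs <- 12000
#' tone <- sin(2 * pi * 3500 * seq(0, 1, by = 1 / fs)) * sqrt(2) * 1e7
#' ps <- pressure_series(tone, fs)
#' ps
#' @export
pressure_series <- function(samples, sample_rate_hz, start_time_s = 0) {
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  assert_scalar_number(start_time_s, "start_time_s")
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort("`samples` must be finite (calibrated pressure in micropascal).")
  }
  structure(
    list(
      samples = samples,
      sample_rate_hz = sample_rate_hz,
      start_time_s = start_time_s
    ),
    class = "pressure_series"
  )
}

#' @export
print.pressure_series <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate_hz
  cat(sprintf(
    "<pressure_series: %d samples @ %g Hz (%.2f s), start %.2f s>\n",
    length(x$samples), x$sample_rate_hz, dur, x$start_time_s
  ))
  rms <- sqrt(mean(x$samples^2))
  if (rms > 0) cat(sprintf("  broadband SPL %.1f dB re 1 uPa\n", db_spl(rms)))
  invisible(x)
}

#' @export
as_tibble.pressure_series <- function(x, ...) {
  tibble(
    t_s = x$start_time_s + (seq_along(x$samples) - 1) / x$sample_rate_hz,
    p_upa = x$samples
  )
}

#' @export
length.pressure_series <- function(x) length(x$samples)

ps_duration <- function(x) length(x$samples) / x$sample_rate_hz

ps_end_time <- function(x) x$start_time_s + ps_duration(x)
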