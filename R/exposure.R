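# Received-level and sound-exposure metrics from calibrated pressure
# records: third-octave band SPL over short windows (with optional rejection
# of transient echolocation clicks), per-ping sound exposure level over a
# fixed energy window, cumulative SEL across a ping train, and a pluggable
# geometric-spreading + absorption transmission-loss model for predicting
# received levels from source parameters.

#' Third-octave analysis bands
#'
#' The four adjacent 1/3-octave bands spanning roughly 2-5 kHz used for
#' mid-frequency playback analysis, with edge frequencies 1960, 2467, 3111,
#' 3920 and 4939 Hz (adjacent edges in ratio 2^(1/3)).
#'
#' @param edges_hz Strictly increasing vector of band edge frequencies.
#' @return A tibble with `low_hz`, `high_hz`, one row per band.
#' @export
third_octave_bands <- function(edges_hz = c(1960, 2467, 3111, 3920, 4939)) {
  if (length(edges_hz) < 2 || any(diff(edges_hz) <= 0)) {
    abort("`edges_hz` must be strictly increasing with at least 2 values.")
  }
  ratio <- edges_hz[-1] / edges_hz[-length(edges_hz)]
  if (any(abs(ratio / 2^(1 / 3) - 1) > 0.01)) {
    abort("Adjacent band edges must be in ratio 2^(1/3) within 1%.")
  }
  tibble(low_hz = edges_hz[-length(edges_hz)], high_hz = edges_hz[-1])
}

# Zero-phase Butterworth band-pass (8-pole, ~48 dB/octave roll-off per side,
# i.e. >= 40 dB one octave outside the band; filtfilt doubles that and keeps
# SPL timing aligned with the transmit schedule).
band_filter <- function(series, band) {
  fs <- series$sample_rate_hz
  if (band[1] <= 0 || band[2] >= fs / 2) {
    abort(sprintf("Band %g-%g Hz outside (0, Nyquist = %g Hz).",
                  band[1], band[2], fs / 2))
  }
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, series$samples)
}

new_spl_series <- function(df, band, window_s) {
  attr(df, "band") <- band
  attr(df, "window_s") <- window_s
  class(df) <- c("spl_series", class(df))
  df
}

#' Band sound pressure level over sliding windows
#'
#' Band-limits the record with a zero-phase Butterworth filter (>= 40 dB
#' rejection one octave outside the band) and computes RMS SPL over sliding
#' windows. With `click_reject = TRUE` (meaningful for the 200-ms window),
#' 10-ms sub-frames whose level exceeds the window median by more than 10 dB
#' are excluded from the average, suppressing energy from short echolocation
#' clicks of the tagged whale itself.
#'
#' @param series A [pressure_series()].
#' @param band Numeric `c(low_hz, high_hz)`.
#' @param window_s RMS window length in seconds (typically 0.010 or 0.200).
#' @param hop_s Window hop; defaults to `window_s / 2`.
#' @param click_reject Reject transient-dominated sub-frames?
#' @param subframe_s Sub-frame length used by click rejection.
#' @param reject_db Rejection threshold above the window median, dB.
#' @return A tibble (`spl_series`) with `time_s` (window start) and
#'   `spl_db`; silent windows give `NA`.
#' @examples
#' fs <- 12000
#' tone <- sqrt(2) * 1e7 * sin(2 * pi * 3500 * seq(0, 1, by = 1 / fs))
#' ss <- band_spl(pressure_series(tone, fs), c(3111, 3920))
#' round(max(ss$spl_db, na.rm = TRUE), 1)
#' @export
band_spl <- function(series, band, window_s = 0.200, hop_s = window_s / 2,
                     click_reject = FALSE, subframe_s = 0.010,
                     reject_db = 10) {
  if (!inherits(series, "pressure_series")) {
    abort("`series` must be a pressure_series.")
  }
  fs <- series$sample_rate_hz
  wlen <- round(window_s * fs)
  if (wlen < 8) abort("`window_s` must cover at least 8 samples.")
  x <- band_filter(series, band)
  n <- length(x)
  hop <- max(1L, round(hop_s * fs))
  starts <- seq(1L, n - wlen + 1L, by = hop)
  cs <- c(0, cumsum(x^2))
  if (click_reject) {
    sub <- max(2L, round(subframe_s * fs))
    ms <- vapply(starts, function(s) {
      # interior sub-frames plus one look-ahead/behind frame, so transients
      # sitting just outside the window still trigger the guard
      sf_starts <- seq(s - sub, s + wlen, by = sub)
      valid <- sf_starts >= 1 & sf_starts + sub <= n + 1
      sf_starts <- sf_starts[valid]
      interior <- sf_starts >= s & sf_starts + sub <= s + wlen
      sub_ms <- (cs[sf_starts + sub] - cs[sf_starts]) / sub
      med <- median(sub_ms[interior])
      hot <- which(sub_ms > med * 10^(reject_db / 10))
      # guard frames either side of a transient absorb band-filter ring-down
      drop <- unique(c(hot, hot - 1L, hot + 1L))
      keep <- setdiff(which(interior), drop)
      mean(sub_ms[keep])
    }, numeric(1))
  } else {
    ms <- (cs[starts + wlen] - cs[starts]) / wlen
  }
  df <- tibble(
    time_s = series$start_time_s + (starts - 1) / fs,
    spl_db = db_spl(sqrt(pmax(ms, 0)))
  )
  new_spl_series(df, band, window_s)
}

#' Maximum received level across third-octave bands
#'
#' Computes [band_spl()] in each band on a common window grid and takes the
#' pointwise maximum, the rule used for broadband stimuli such as killer
#' whale call playbacks that spread energy across several 1/3-octave bands.
#'
#' @param series A [pressure_series()].
#' @param bands Band tibble from [third_octave_bands()] (>= 2 bands).
#' @inheritParams band_spl
#' @return An `spl_series` tibble with `time_s`, `spl_db` and `band`
#'   (which band supplied the maximum at each window).
#' @export
max_band_rl <- function(series, bands = third_octave_bands(),
                        window_s = 0.200, hop_s = window_s / 2,
                        click_reject = FALSE) {
  assert_cols(bands, c("low_hz", "high_hz"))
  if (nrow(bands) < 2) abort("Need at least 2 bands.")
  per_band <- purrr::pmap(bands, function(low_hz, high_hz) {
    band_spl(series, c(low_hz, high_hz), window_s = window_s, hop_s = hop_s,
             click_reject = click_reject)$spl_db
  })
  mat <- do.call(cbind, per_band)
  all_na <- apply(mat, 1, function(r) all(is.na(r)))
  best <- rep(NA_integer_, nrow(mat))
  best[!all_na] <- apply(mat[!all_na, , drop = FALSE], 1, which.max)
  spl <- rep(NA_real_, nrow(mat))
  spl[!all_na] <- mat[cbind(which(!all_na), best[!all_na])]
  tmpl <- band_spl(series, unlist(bands[1, ]), window_s = window_s,
                   hop_s = hop_s)
  df <- tibble(
    time_s = tmpl$time_s,
    spl_db = spl,
    band = ifelse(is.na(best), NA_character_,
                  sprintf("%g-%g", bands$low_hz[best], bands$high_hz[best]))
  )
  new_spl_series(df, c(min(bands$low_hz), max(bands$high_hz)), window_s)
}

#' Sound exposure level of a transmission over a fixed energy window
#'
#' Integrates band-limited squared pressure over a window starting at each
#' `ping_start_s` (2 s by default, long enough to include early multipath
#' arrivals): `SEL = 10 log10( sum(p^2) / fs )` in dB re 1 uPa^2 s.
#'
#' @param series A [pressure_series()].
#' @param ping_start_s Vector of window start times, seconds.
#' @param window_s Energy window length, seconds.
#' @param band Optional `c(low_hz, high_hz)` band limit.
#' @return Numeric vector of SEL values, dB re 1 uPa^2 s.
#' @export
ping_sel <- function(series, ping_start_s, window_s = 2.0, band = NULL) {
  if (!inherits(series, "pressure_series")) {
    abort("`series` must be a pressure_series.")
  }
  fs <- series$sample_rate_hz
  x <- if (is.null(band)) series$samples else band_filter(series, band)
  wlen <- round(window_s * fs)
  i0 <- round((ping_start_s - series$start_time_s) * fs) + 1L
  if (any(i0 < 1L) || any(i0 + wlen - 1L > length(x))) {
    abort("SEL window extends outside the record (no partial windows).")
  }
  cs <- c(0, cumsum(x^2))
  energy <- (cs[i0 + wlen] - cs[i0]) / fs
  db_from_energy(energy)
}

#' Cumulative sound exposure level across a ping train
#'
#' @param sel_db Vector of per-ping SEL values, dB re 1 uPa^2 s, in ping
#'   order.
#' @return Vector of running cumulative SEL; the last element is the overall
#'   SEL of the exposure.
#' @examples
#' cumulative_sel(c(120, 120))  # 120 + 10*log10(2)
#' @export
cumulative_sel <- function(sel_db) {
  if (length(sel_db) == 0) abort("`sel_db` must be nonempty.")
  db_from_energy(cumsum(10^(sel_db / 10)))
}

#' Transmission-loss model: geometric spreading plus absorption
#'
#' A deliberately simple range-dependent loss law,
#' `TL = geometric_coeff * log10(range_m) + absorption_db_per_km * range_km`,
#' defaulting to spherical spreading (20 log10 R) with 0.2 dB/km absorption,
#' appropriate near 3.5 kHz. It stands in for full ocean propagation
#' modelling, which is outside the scope of this package.
#'
#' @param geometric_coeff Spreading coefficient, dB per decade of range.
#' @param absorption_db_per_km Absorption at the band centre, dB/km.
#' @return An object of class `tl_model`.
#' @export
transmission_loss_model <- function(geometric_coeff = 20,
                                    absorption_db_per_km = 0.2) {
  if (geometric_coeff < 0 || absorption_db_per_km < 0) {
    abort("Transmission-loss coefficients must be >= 0.")
  }
  structure(
    list(geometric_coeff = geometric_coeff,
         absorption_db_per_km = absorption_db_per_km),
    class = "tl_model"
  )
}

transmission_loss <- function(range_m, model) {
  model$geometric_coeff * log10(range_m) +
    model$absorption_db_per_km * range_m / 1000
}

#' Predict received level from source level and range
#'
#' `RL = SL - TL(range)` with the transmission loss from
#' [transmission_loss_model()]. Range is referenced to 1 m (where TL from
#' the geometric term is zero).
#'
#' @param source_level_db Source level, dB re 1 uPa at 1 m.
#' @param range_m Source-receiver range in meters (>= 1).
#' @param model A [transmission_loss_model()].
#' @return Received level, dB re 1 uPa.
#' @examples
#' predict_rl(212, 10000)  # 212 - 80 - 2 = 130
#' @export
predict_rl <- function(source_level_db, range_m,
                       model = transmission_loss_model()) {
  if (any(range_m < 1)) abort("`range_m` must be >= 1.")
  source_level_db - transmission_loss(range_m, model)
}

#' Per-ping exposure metrics for a playback ping train
#'
#' For each scheduled transmission, finds the maximum 200-ms band SPL within
#' a search interval after the scheduled time, computes the ping SEL over a
#' fixed energy window anchored at the detected ping onset, and accumulates
#' cumulative SEL across the train. The onset is taken as the earliest SPL
#' window in the search interval whose level is within `onset_tol_db` of the
#' per-ping peak (robust against composite pings whose loudest window falls
#' late in the transmission); the energy window starts `anchor_offset_s`
#' before that onset so the direct arrival is fully contained.
#'
#' @param series A [pressure_series()].
#' @param ping_times_s Scheduled transmission times, seconds.
#' @param band `c(low_hz, high_hz)` analysis band.
#' @param window_s SPL window, seconds.
#' @param hop_s SPL window hop; small values localize the peak better.
#' @param sel_window_s Energy window for per-ping SEL, seconds.
#' @param anchor_offset_s Lead time of the SEL window before the detected
#'   onset, seconds.
#' @param onset_tol_db Onset detection: earliest window within this many dB
#'   of the per-ping SPL peak.
#' @param search_s Length of the per-ping search interval, seconds.
#' @param click_reject Passed to [band_spl()].
#' @return A tibble (`ping_exposure`) with `ping_index`, `time_s` (SPL peak
#'   window), `max_spl_200ms_db`, `sel_db`, `cum_sel_db`.
#' @export
ping_exposure <- function(series, ping_times_s, band, window_s = 0.200,
                          hop_s = 0.010, sel_window_s = 2.0,
                          anchor_offset_s = 0.200, onset_tol_db = 3,
                          search_s = 2.0, click_reject = FALSE) {
  spl <- band_spl(series, band, window_s = window_s, hop_s = hop_s,
                  click_reject = click_reject)
  res <- purrr::map_dfr(seq_along(ping_times_s), function(k) {
    t0 <- ping_times_s[k]
    in_win <- spl$time_s >= t0 & spl$time_s < t0 + search_s
    if (!any(in_win) || all(is.na(spl$spl_db[in_win]))) {
      return(tibble(ping_index = k, time_s = NA_real_,
                    max_spl_200ms_db = NA_real_, sel_db = NA_real_))
    }
    sub <- spl[in_win, ]
    i <- which.max(sub$spl_db)
    peak <- sub$spl_db[i]
    i_on <- which(sub$spl_db >= peak - onset_tol_db)[1]
    t_sel <- max(series$start_time_s, sub$time_s[i_on] - anchor_offset_s)
    t_sel <- min(t_sel, ps_end_time(series) - sel_window_s)
    tibble(
      ping_index = k,
      time_s = sub$time_s[i],
      max_spl_200ms_db = sub$spl_db[i],
      sel_db = ping_sel(series, t_sel, window_s = sel_window_s, band = band)
    )
  })
  res$cum_sel_db <- cumulative_sel(res$sel_db)
  class(res) <- c("ping_exposure", class(res))
  res
}

#' @export
glance.ping_exposure <- function(x, ...) {
  tibble(
    n_pings = nrow(x),
    max_spl_db = max(x$max_spl_200ms_db, na.rm = TRUE),
    overall_sel_db = x$cum_sel_db[nrow(x)]
  )
}

#' @export
autoplot.ping_exposure <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("ping_index", "max_spl_200ms_db", "cum_sel_db")],
    cols = c("max_spl_200ms_db", "cum_sel_db"),
    names_to = "metric", values_to = "level_db"
  )
  df$metric <- dplyr::recode(df$metric,
    max_spl_200ms_db = "max 200-ms SPL (dB re 1 uPa)",
    cum_sel_db = "cumulative SEL (dB re 1 uPa^2 s)"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ping_index, y = .data$level_db,
                                   colour = .data$metric)) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_colour_manual(values = c(
      "max 200-ms SPL (dB re 1 uPa)" = "blue",
      "cumulative SEL (dB re 1 uPa^2 s)" = "red"
    )) +
    ggplot2::labs(x = "ping", y = "level (dB)", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' @export
autoplot.spl_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$spl_db)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "time (s)", y = "SPL (dB re 1 uPa)",
      title = sprintf("band %g-%g Hz, %g-ms window",
                      attr(object, "band")[1], attr(object, "band")[2],
                      1000 * attr(object, "window_s"))
    ) +
    ggplot2::theme_minimal()
}
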