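# Small in-code fixtures shared across tests.

# Regular square array with unit-free coordinates in meters.
square_array <- function(n_side = 3, spacing_m = 4000) {
  g <- expand.grid(ix = seq_len(n_side) - 1, iy = seq_len(n_side) - 1)
  tibble::tibble(
    phone_id = sprintf("H%03d", seq_len(nrow(g))),
    x_m = g$ix * spacing_m,
    y_m = g$iy * spacing_m,
    depth_m = 1500
  )
}

# One click-train event row.
train <- function(phone, start, end, n, species = "Md") {
  tibble::tibble(phone_id = phone, start_s = start, end_s = end,
                 n_clicks = as.integer(n), species = species)
}

# Phase table for a two-phase observation, durations in hours.
two_phases <- function(h_a, h_b, names = c("before", "during")) {
  observation_phases(names, c(0, h_a) * 3600, c(h_a, h_a + h_b) * 3600)
}

# Constant-amplitude tone series with a given band RMS SPL.
tone_series <- function(spl_db, freq_hz = 3500, dur_s = 1, fs = 16000) {
  t <- seq(0, dur_s, by = 1 / fs)
  pressure_series(sqrt(2) * upa_from_db(spl_db) * sin(2 * pi * freq_hz * t), fs)
}

# Straight-line track of n fixes moving at a constant speed along a meridian.
straight_track <- function(n = 10, speed_mps = 1, dt_s = 3600,
                           lat0 = 24.5, lon0 = -77.5) {
  km_per_deg <- 6371 * pi / 180
  step_deg <- speed_mps * dt_s / 1000 / km_per_deg
  tibble::tibble(
    time = as.POSIXct("2009-05-07 00:00:00", tz = "UTC") +
      (seq_len(n) - 1) * dt_s,
    lat = lat0 + (seq_len(n) - 1) * step_deg,
    lon = lon0
  )
}
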