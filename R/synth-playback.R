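# Synthetic playback stimulus generation and reception. Reproduces the
# structure of a dose-escalation playback: a short composite ping repeated
# at a fixed interval, with source level ramping up in fixed steps until a
# maximum, received through a geometric-spreading + absorption loss law on
# top of Gaussian background noise. Ground-truth per-ping received levels
# and energies are retained so exposure metrics can be validated end to end.

#' Playback stimulus schedules
#'
#' Returns the stimulus definition for one of the three playback types:
#' \describe{
#'   \item{MFA}{simulated mid-frequency sonar: 0.5-s upsweep 3.2-3.3 kHz,
#'     0.5-s tone at 3.43 kHz, 0.1-s silence, 0.3-s tone at 3.75 kHz
#'     (1.4 s overall), repeated every 25 s; ramp-up from 152 dB source
#'     level in 3-dB steps every 25 s to a 212-dB maximum.}
#'   \item{PRN}{pseudorandom noise matched to MFA in band and timing:
#'     1.0 s of 3.2-3.75 kHz noise, 0.1-s silence, 0.3 s of noise
#'     (1.4 s overall), same repetition; ramp-up from 160 dB in 3-dB steps
#'     to 211 dB.}
#'   \item{ORCA}{band-limited killer whale call stand-in: a 0.75-s sweep
#'     across 2-5 kHz repeated every 30 s; ramp-up from 135 dB in 5-dB
#'     steps every 30 s to a 196-dB maximum.}
#' }
#' Segment kinds are `sweep`, `tone`, `noise` or `silence`, each with a
#' duration and a frequency band (`band_hz` is `c(f, f)` for a tone).
#'
#' @param stimulus One of `"MFA"`, `"PRN"`, `"ORCA"`.
#' @param n_pings Number of transmissions.
#' @param start_sl_db,ramp_step_db,ramp_step_interval_s,max_sl_db Ramp-up
#'   parameters (dB re 1 uPa at 1 m); defaults depend on the stimulus.
#' @param repeat_interval_s Ping repetition interval, seconds.
#' @return An object of class `playback_schedule`: list with `stimulus`,
#'   `segments` (tibble `duration_s`, `kind`, `band_hz` list-column),
#'   `ping_duration_s`, `repeat_interval_s`, ramp fields and a `pings`
#'   tibble (`ping_index`, `time_s`, `sl_db`).
#' @examples
#' sched <- playback_schedule("MFA", n_pings = 5)
#' sched$pings
#' @export
playback_schedule <- function(stimulus = c("MFA", "PRN", "ORCA"),
                              n_pings = 10,
                              start_sl_db = NULL, ramp_step_db = NULL,
                              ramp_step_interval_s = NULL, max_sl_db = NULL,
                              repeat_interval_s = NULL) {
  stimulus <- match.arg(stimulus)
  defs <- switch(stimulus,
    MFA = list(
      segments = tibble(
        duration_s = c(0.5, 0.5, 0.1, 0.3),
        kind = c("sweep", "tone", "silence", "tone"),
        band_hz = list(c(3200, 3300), c(3430, 3430), NULL, c(3750, 3750))
      ),
      start_sl_db = 152, ramp_step_db = 3, ramp_step_interval_s = 25,
      max_sl_db = 212, repeat_interval_s = 25
    ),
    PRN = list(
      segments = tibble(
        duration_s = c(1.0, 0.1, 0.3),
        kind = c("noise", "silence", "noise"),
        band_hz = list(c(3200, 3750), NULL, c(3200, 3750))
      ),
      start_sl_db = 160, ramp_step_db = 3, ramp_step_interval_s = 25,
      max_sl_db = 211, repeat_interval_s = 25
    ),
    ORCA = list(
      segments = tibble(
        duration_s = 0.75,
        kind = "sweep",
        band_hz = list(c(2000, 5000))
      ),
      start_sl_db = 135, ramp_step_db = 5, ramp_step_interval_s = 30,
      max_sl_db = 196, repeat_interval_s = 30
    )
  )
  start_sl_db <- start_sl_db %||% defs$start_sl_db
  ramp_step_db <- ramp_step_db %||% defs$ramp_step_db
  ramp_step_interval_s <- ramp_step_interval_s %||% defs$ramp_step_interval_s
  max_sl_db <- max_sl_db %||% defs$max_sl_db
  repeat_interval_s <- repeat_interval_s %||% defs$repeat_interval_s
  if (start_sl_db > max_sl_db) abort("`start_sl_db` must be <= `max_sl_db`.")
  ping_duration_s <- sum(defs$segments$duration_s)
  if (repeat_interval_s <= ping_duration_s) {
    abort("`repeat_interval_s` must exceed the ping duration.")
  }
  t <- (seq_len(n_pings) - 1) * repeat_interval_s
  sl <- pmin(start_sl_db + ramp_step_db * floor(t / ramp_step_interval_s),
             max_sl_db)
  structure(
    list(
      stimulus = stimulus,
      segments = defs$segments,
      ping_duration_s = ping_duration_s,
      repeat_interval_s = repeat_interval_s,
      start_sl_db = start_sl_db, ramp_step_db = ramp_step_db,
      ramp_step_interval_s = ramp_step_interval_s, max_sl_db = max_sl_db,
      pings = tibble(ping_index = seq_len(n_pings), time_s = t, sl_db = sl)
    ),
    class = "playback_schedule"
  )
}

# One ping waveform with every active segment at RMS pressure p_rms (uPa).
synth_ping <- function(segments, p_rms, fs) {
  purrr::pmap(segments, function(duration_s, kind, band_hz) {
    m <- round(duration_s * fs)
    tt <- (seq_len(m) - 1) / fs
    switch(kind,
      silence = rep(0, m),
      tone = sqrt(2) * p_rms * sin(2 * pi * band_hz[1] * tt),
      sweep = {
        f0 <- band_hz[1]; f1 <- band_hz[2]
        phase <- 2 * pi * (f0 * tt + (f1 - f0) / (2 * duration_s) * tt^2)
        sqrt(2) * p_rms * sin(phase)
      },
      noise = {
        x <- rnorm(m)
        bf <- signal::butter(4, band_hz / (fs / 2), type = "pass")
        x <- signal::filtfilt(bf, x)
        x / sqrt(mean(x^2)) * p_rms
      },
      abort(sprintf("Unknown segment kind '%s'.", kind))
    )
  }) |> unlist()
}

#' Simulate reception of a playback ping train on a tag
#'
#' Synthesizes a calibrated pressure record containing the scheduled ping
#' train at received level `SL(t) - TL(range)` over Gaussian background
#' noise, and retains ground truth (per-ping received SPL and SEL and the
#' running cumulative SEL). Each active segment of a ping is generated at
#' constant RMS equal to the received level, so the true maximum 200-ms SPL
#' of a ping equals its received level and its true SEL is
#' `RL + 10 log10(active duration)`.
#'
#' @param schedule A [playback_schedule()].
#' @param range_m Source-whale range per ping, meters (scalar or one per
#'   ping); must be > 0.
#' @param tl_model A [transmission_loss_model()].
#' @param noise_floor_db Broadband RMS level of the Gaussian background,
#'   dB re 1 uPa.
#' @param sample_rate_hz Sampling rate; must be at least twice the highest
#'   stimulus frequency.
#' @param tail_s Extra record time after the final ping, seconds.
#' @param seed Optional integer seed.
#' @return A list with `series` (a [pressure_series()]) and `truth` (tibble
#'   `ping_index`, `time_s`, `sl_db`, `rl_db`, `sel_db`, `cum_sel_db`).
#' @export
simulate_playback_reception <- function(schedule, range_m,
                                        tl_model = transmission_loss_model(),
                                        noise_floor_db = 60,
                                        sample_rate_hz = 24000,
                                        tail_s = 3, seed = NULL) {
  if (!inherits(schedule, "playback_schedule")) {
    abort("`schedule` must be a playback_schedule.")
  }
  if (any(range_m <= 0)) abort("`range_m` must be > 0.")
  fs <- sample_rate_hz
  f_max <- max(unlist(schedule$segments$band_hz))
  if (fs < 2 * f_max) {
    abort(sprintf("`sample_rate_hz` must be >= %g Hz (2 x upper band edge).",
                  2 * f_max))
  }
  if (!is.null(seed)) set.seed(seed)
  pings <- schedule$pings
  n_pings <- nrow(pings)
  range_m <- rep_len(range_m, n_pings)
  rl <- pings$sl_db - transmission_loss(range_m, tl_model)

  total_s <- max(pings$time_s) + schedule$ping_duration_s + tail_s
  n <- round(total_s * fs)
  x <- rnorm(n, sd = upa_from_db(noise_floor_db))
  active_s <- sum(schedule$segments$duration_s[schedule$segments$kind != "silence"])
  for (k in seq_len(n_pings)) {
    w <- synth_ping(schedule$segments, upa_from_db(rl[k]), fs)
    i0 <- round(pings$time_s[k] * fs) + 1L
    idx <- i0:(i0 + length(w) - 1L)
    x[idx] <- x[idx] + w
  }
  sel_true <- rl + 10 * log10(active_s)
  list(
    series = pressure_series(x, fs),
    truth = tibble(
      ping_index = pings$ping_index,
      time_s = pings$time_s,
      sl_db = pings$sl_db,
      range_m = range_m,
      rl_db = rl,
      sel_db = sel_true,
      cum_sel_db = cumulative_sel(sel_true)
    )
  )
}
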