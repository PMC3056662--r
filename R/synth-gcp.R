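# Synthetic click-train event streams for a hydrophone array. Each whale
# group performs synchronized deep foraging dives about once every two
# hours, clicking for about half an hour per dive; during a bout, click
# trains are detected off and on (as the clicking whales scan their narrow
# beam) at every hydrophone within the detection radius of the group. An
# optional avoidance rule relocates dives away from a designated point
# during a flagged phase, emulating displacement from an ensonified area.

#' Simulate a click-train event stream with ground truth
#'
#' @param array Hydrophone array tibble from [generate_array()].
#' @param total_duration_s Length of the simulated observation, seconds.
#' @param n_groups Number of independently foraging groups.
#' @param phases Optional phase tibble from [observation_phases()]; must
#'   tile `[0, total_duration_s]`. Defaults to one `baseline` phase.
#' @param dive_interval_s Mean time between dive starts per group, seconds.
#' @param clicking_duration_s Mean clicking-bout duration, seconds.
#' @param detection_radius_m Maximum click detection range, meters.
#' @param move_speed_mps Group travel speed between dives, m/s.
#' @param on_s,off_s Mean on/off sub-interval durations of intermittent
#'   detection within a bout, seconds. The within-bout duty cycle is not a
#'   measured quantity; it is exposed rather than fixed.
#' @param click_rate_hz Mean click rate while a train is detected.
#' @param avoidance Optional list `list(phase =, center = c(x_m, y_m),
#'   d_min_m =, p_suppress =)`: dives starting in the flagged phase are
#'   relocated at least `d_min_m` from `center`, and a fraction
#'   `p_suppress` (default 0) are suppressed entirely, emulating cessation
#'   of foraging.
#' @param seed Optional integer seed.
#' @return A list with `events` (tibble `phone_id`, `start_s`, `end_s`,
#'   `n_clicks`, `species`) and `truth` (tibble `group`, `dive`, `start_s`,
#'   `end_s`, `x_m`, `y_m`, `phase`, `phones` list-column).
#' @export
simulate_gcp_stream <- function(array, total_duration_s, n_groups = 5,
                                phases = NULL,
                                dive_interval_s = 7200,
                                clicking_duration_s = 1800,
                                detection_radius_m = 6500,
                                move_speed_mps = 1.0,
                                on_s = 30, off_s = 20,
                                click_rate_hz = 2.5,
                                avoidance = NULL, seed = NULL) {
  assert_cols(array, c("phone_id", "x_m", "y_m"))
  if (nrow(array) == 0) abort("`array` must contain at least one phone.")
  assert_scalar_number(total_duration_s, "total_duration_s", positive = TRUE)
  if (is.null(phases)) {
    phases <- observation_phases("baseline", 0, total_duration_s)
  }
  if (abs(min(phases$start_s)) > 1e-9 ||
      abs(max(phases$end_s) - total_duration_s) > 1e-6 ||
      (nrow(phases) > 1 &&
       any(abs(phases$start_s[-1] - phases$end_s[-nrow(phases)]) > 1e-6))) {
    abort("`phases` must tile [0, total_duration_s].")
  }
  if (!is.null(seed)) set.seed(seed)

  xr <- range(array$x_m)
  yr <- range(array$y_m)
  empty_events <- tibble(phone_id = character(), start_s = numeric(),
                         end_s = numeric(), n_clicks = integer(),
                         species = character())
  empty_truth <- tibble(group = integer(), dive = integer(),
                        start_s = numeric(), end_s = numeric(),
                        x_m = numeric(), y_m = numeric(),
                        phase = character(), phones = list())
  if (n_groups == 0) return(list(events = empty_events, truth = empty_truth))

  relocate <- function(x, y) {
    # resample until the dive centroid is >= d_min from the avoidance centre
    for (i in 1:200) {
      if (sqrt((x - avoidance$center[1])^2 + (y - avoidance$center[2])^2) >=
          avoidance$d_min_m) {
        return(c(x, y))
      }
      x <- runif(1, xr[1], xr[2])
      y <- runif(1, yr[1], yr[2])
    }
    abort("Avoidance rule could not place a dive >= d_min_m from the centre.")
  }

  events <- list()
  truth <- list()
  for (g in seq_len(n_groups)) {
    x <- runif(1, xr[1], xr[2])
    y <- runif(1, yr[1], yr[2])
    t_dive <- runif(1, 0, dive_interval_s)
    dive_no <- 0
    while (t_dive < total_duration_s) {
      bout_len <- clicking_duration_s * runif(1, 0.9, 1.1)
      bout_end <- min(t_dive + bout_len, total_duration_s)
      phase_i <- assign_phase(t_dive, phases)
      ph_name <- phases$phase[phase_i]
      suppressed <- FALSE
      if (!is.null(avoidance) && identical(ph_name, avoidance$phase)) {
        p_sup <- avoidance$p_suppress %||% 0
        suppressed <- runif(1) < p_sup
        xy <- relocate(x, y)
        x <- xy[1]; y <- xy[2]
      }
      if (suppressed) {
        gap <- dive_interval_s * runif(1, 0.85, 1.15)
        ang <- runif(1, 0, 2 * pi)
        step <- move_speed_mps * gap
        x <- min(max(x + step * cos(ang), xr[1]), xr[2])
        y <- min(max(y + step * sin(ang), yr[1]), yr[2])
        t_dive <- t_dive + gap
        next
      }
      d <- sqrt((array$x_m - x)^2 + (array$y_m - y)^2)
      det <- which(d <= detection_radius_m)
      if (length(det) > 0) {
        dive_no <- dive_no + 1
        nearest <- det[which.min(d[det])]
        ev <- purrr::map_dfr(det, function(k) {
          make_bout_events(
            t_dive, bout_end, on_s, off_s, click_rate_hz,
            anchored = (k == nearest)
          ) |>
            dplyr::mutate(phone_id = array$phone_id[k], .before = 1)
        })
        events[[length(events) + 1]] <- ev
        truth[[length(truth) + 1]] <- tibble(
          group = g, dive = dive_no, start_s = t_dive, end_s = bout_end,
          x_m = x, y_m = y, phase = ph_name,
          phones = list(sort(array$phone_id[det]))
        )
      }
      # travel to the next dive site
      gap <- dive_interval_s * runif(1, 0.85, 1.15)
      ang <- runif(1, 0, 2 * pi)
      step <- move_speed_mps * gap
      x <- min(max(x + step * cos(ang), xr[1]), xr[2])
      y <- min(max(y + step * sin(ang), yr[1]), yr[2])
      t_dive <- t_dive + gap
    }
  }
  if (length(events) == 0) return(list(events = empty_events,
                                       truth = empty_truth))
  events <- dplyr::bind_rows(events)
  events$species <- "Md"
  events <- dplyr::arrange(events, .data$start_s, .data$phone_id)
  list(events = events,
       truth = dplyr::arrange(dplyr::bind_rows(truth), .data$start_s))
}

# Alternating on/off detection sub-intervals across one clicking bout on
# one phone. The anchored phone (nearest to the group) is detected from the
# first moment of the bout and through its end, pinning the true GCP
# boundaries; other phones start at a random offset.
make_bout_events <- function(t0, t1, on_s, off_s, click_rate_hz, anchored) {
  starts <- numeric(0)
  ends <- numeric(0)
  t <- if (anchored) t0 else t0 + runif(1, 0, off_s)
  while (t < t1) {
    on <- on_s * runif(1, 0.5, 1.5)
    e <- min(t + on, t1)
    starts <- c(starts, t)
    ends <- c(ends, e)
    t <- e + off_s * runif(1, 0.5, 1.5)
  }
  if (anchored && (length(ends) == 0 || ends[length(ends)] < t1)) {
    starts <- c(starts, max(t0, t1 - on_s))
    ends <- c(ends, t1)
  }
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  tibble(
    start_s = starts,
    end_s = ends,
    n_clicks = as.integer(pmax(5, round(click_rate_hz * (ends - starts) *
                                          runif(length(starts), 0.7, 1.1))))
  )
}

#' Simulate GCP start times as a phase-inhomogeneous Poisson process
#'
#' Draws group clicking periods directly as a Poisson process with a given
#' rate per phase, for studying the rate statistics in isolation from the
#' detector (e.g. power and type-I error of the randomization test).
#'
#' @param phases Phase tibble from [observation_phases()].
#' @param rate_per_h One rate per phase, GCPs per hour.
#' @param duration_s Nominal GCP duration used for `end_s`, seconds.
#' @param seed Optional integer seed.
#' @return A GCP-like tibble with `start_s`, `end_s`, sorted by `start_s`.
#' @export
simulate_phase_gcps <- function(phases, rate_per_h, duration_s = 1800,
                                seed = NULL) {
  assert_cols(phases, c("phase", "start_s", "end_s", "duration_h"))
  if (length(rate_per_h) != nrow(phases)) {
    abort("Need one `rate_per_h` per phase.")
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- unlist(purrr::map(seq_len(nrow(phases)), function(i) {
    n <- rpois(1, rate_per_h[i] * phases$duration_h[i])
    sort(runif(n, phases$start_s[i], phases$end_s[i]))
  }))
  tibble(start_s = sort(starts), end_s = sort(starts) + duration_s)
}
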