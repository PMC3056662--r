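# Synthetic deep foraging dive profiles. A dive is generated directly from
# the eleven per-dive parameters used in response analysis, so that
# re-extracting parameters from the simulated depth series and audit events
# recovers the inputs (a round-trip identity used heavily in tests).
#
# Dive boundaries are expressed at the surface-threshold crossing: "leaving
# the surface" is operationalized identically in generation and analysis as
# the depth series crossing `surface_threshold_m`, so the generated profile
# crosses the threshold exactly at the nominal boundary times. Per the field
# definitions, descent rate is the depth at first click divided by descent
# duration (an average from the surface, not an instantaneous slope), and
# ascent rate is the depth at last click divided by the silent ascent
# duration.

#' Construct a table of dive parameters
#'
#' Builds the per-dive parameter table used by [simulate_dive_profile()] and
#' returned by [compute_dive_parameters()]. Derived fields (`buzz_rate_per_s`
#' and `dive_duration_s`) are filled in; internal consistency is checked and
#' violations are reported by name.
#'
#' @param pre_dive_interval_s Surface interval before the dive, seconds.
#' @param descent_rate_mps Depth at first click / descent duration, m/s.
#' @param descent_duration_s Surface-leave to first click, seconds.
#' @param clicking_duration_s First click to last click, seconds.
#' @param n_buzzes Number of terminal buzzes (prey-capture attempts).
#' @param dive_depth_m Maximum dive depth, meters.
#' @param ascent_rate_mps Depth at last click / silent ascent duration, m/s.
#' @param silent_ascent_duration_s Last click to surfacing, seconds.
#' @param post_dive_interval_s Surface interval after the dive, seconds.
#' @return A tibble with the eleven dive parameters, one row per dive.
#' @export
dive_params <- function(pre_dive_interval_s = 3600,
                        descent_rate_mps = 1.4,
                        descent_duration_s = 700,
                        clicking_duration_s = 1800,
                        n_buzzes = 25,
                        dive_depth_m = 1100,
                        ascent_rate_mps = 0.9,
                        silent_ascent_duration_s = 900,
                        post_dive_interval_s = 3600) {
  p <- tibble(
    pre_dive_interval_s = pre_dive_interval_s,
    descent_rate_mps = descent_rate_mps,
    descent_duration_s = descent_duration_s,
    clicking_duration_s = clicking_duration_s,
    n_buzzes = as.integer(n_buzzes),
    buzz_rate_per_s = as.integer(n_buzzes) / clicking_duration_s,
    dive_depth_m = dive_depth_m,
    ascent_rate_mps = ascent_rate_mps,
    silent_ascent_duration_s = silent_ascent_duration_s,
    dive_duration_s = descent_duration_s + clicking_duration_s +
      silent_ascent_duration_s,
    post_dive_interval_s = post_dive_interval_s
  )
  validate_dive_params(p)
  p
}

validate_dive_params <- function(p) {
  dur_cols <- c("descent_duration_s", "clicking_duration_s",
                "silent_ascent_duration_s")
  for (cl in dur_cols) {
    if (any(p[[cl]] <= 0)) abort(sprintf("`%s` must be > 0.", cl))
  }
  if (any(p$n_buzzes < 0)) abort("`n_buzzes` must be >= 0.")
  d_first <- p$descent_rate_mps * p$descent_duration_s
  d_last <- p$ascent_rate_mps * p$silent_ascent_duration_s
  if (any(d_first > p$dive_depth_m + 1e-9)) {
    abort(paste(
      "Inconsistent parameters: descent_rate_mps * descent_duration_s",
      "(depth at first click) exceeds dive_depth_m."
    ))
  }
  if (any(d_last > p$dive_depth_m + 1e-9)) {
    abort(paste(
      "Inconsistent parameters: ascent_rate_mps * silent_ascent_duration_s",
      "(depth at last click) exceeds dive_depth_m."
    ))
  }
  invisible(p)
}

#' Draw random but internally consistent dive parameters
#'
#' Samples parameter sets typical of deep foraging dives of Blainville's
#' beaked whales: dives of roughly 45-75 min reaching 800-1400 m about once
#' every two hours, with ~30 min of clicking and a few tens of buzzes.
#'
#' @param n Number of dives.
#' @param seed Optional integer seed.
#' @return A dive-parameter tibble (see [dive_params()]).
#' @export
random_dive_params <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  descent_duration_s <- runif(n, 600, 900)
  descent_rate_mps <- runif(n, 1.1, 1.7)
  silent_ascent_duration_s <- runif(n, 700, 1100)
  ascent_rate_mps <- runif(n, 0.7, 1.2)
  d_first <- descent_rate_mps * descent_duration_s
  d_last <- ascent_rate_mps * silent_ascent_duration_s
  dive_depth_m <- pmax(d_first, d_last) * runif(n, 1.05, 1.25)
  # Shared surface interval between consecutive dives (~2-h dive cycle).
  gaps <- runif(n + 1, 3000, 4800)
  dive_params(
    pre_dive_interval_s = gaps[seq_len(n)],
    descent_rate_mps = descent_rate_mps,
    descent_duration_s = descent_duration_s,
    clicking_duration_s = runif(n, 1500, 2100),
    n_buzzes = rpois(n, 25),
    dive_depth_m = dive_depth_m,
    ascent_rate_mps = ascent_rate_mps,
    silent_ascent_duration_s = silent_ascent_duration_s,
    post_dive_interval_s = gaps[seq_len(n) + 1]
  )
}

#' Simulate a tag depth record and audit events from dive parameters
#'
#' Builds a 50-Hz (by default) depth series for one or more consecutive
#' deep foraging dives plus the acoustic-audit events (`click_start`,
#' `click_end`, `buzz`) such that [segment_dives()] followed by
#' [compute_dive_parameters()] recovers the input parameters. For
#' consecutive dives, the pre-dive interval of dive *i+1* must equal the
#' post-dive interval of dive *i* (they are the same surface interval).
#'
#' @param params Dive-parameter tibble ([dive_params()],
#'   [random_dive_params()]), one row per dive in order.
#' @param sample_rate_hz Depth sampling rate, Hz.
#' @param surface_threshold_m Depth defining "at the surface"; the same
#'   value should be used in [segment_dives()].
#' @param depth_noise_sd_m Optional Gaussian sensor noise on depth, meters.
#' @param seed Optional integer seed (used only when noise is added).
#' @return A list with `profile` (tibble `t_s`, `depth_m`), `audit` (tibble
#'   `t_s`, `event`) and `truth` (the input parameters plus dive boundary
#'   times `t_leave_surface_s`, `t_return_surface_s`).
#' @export
simulate_dive_profile <- function(params, sample_rate_hz = 50,
                                  surface_threshold_m = 2,
                                  depth_noise_sd_m = 0, seed = NULL) {
  validate_dive_params(params)
  n_dives <- nrow(params)
  if (n_dives > 1) {
    mism <- abs(params$pre_dive_interval_s[-1] -
                  params$post_dive_interval_s[-n_dives]) > 1e-6
    if (any(mism)) {
      abort(paste(
        "Inconsistent parameters: pre_dive_interval_s of each dive must",
        "equal post_dive_interval_s of the previous dive."
      ))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  thr <- surface_threshold_m
  ramp_s <- 2  # quick passage through the surface layer outside the dive

  # Knot times/depths of the piecewise-linear profile.
  kt <- 0
  kd <- 0
  audit_t <- numeric(0)
  audit_kind <- character(0)
  t_leave <- t_return <- numeric(n_dives)
  t_now <- 0
  for (i in seq_len(n_dives)) {
    p <- params[i, ]
    t_leave[i] <- t_now + p$pre_dive_interval_s
    t_first <- t_leave[i] + p$descent_duration_s
    t_last <- t_first + p$clicking_duration_s
    t_return[i] <- t_last + p$silent_ascent_duration_s
    d_first <- p$descent_rate_mps * p$descent_duration_s
    d_last <- p$ascent_rate_mps * p$silent_ascent_duration_s
    # Apex placed at 40% of the clicking span; shoulder at 70%.
    t_apex <- t_first + 0.4 * p$clicking_duration_s
    t_shld <- t_first + 0.7 * p$clicking_duration_s
    d_shld <- d_last + 0.85 * (p$dive_depth_m - d_last)
    kt <- c(kt, t_leave[i] - ramp_s, t_leave[i], t_first, t_apex, t_shld,
            t_last, t_return[i], t_return[i] + ramp_s)
    kd <- c(kd, 0, thr, d_first, p$dive_depth_m, d_shld, d_last, thr, 0)
    audit_t <- c(audit_t, t_first,
                 if (p$n_buzzes > 0) {
                   t_first + p$clicking_duration_s *
                     (seq_len(p$n_buzzes) - 0.5) / p$n_buzzes
                 },
                 t_last)
    audit_kind <- c(audit_kind, "click_start",
                    rep("buzz", p$n_buzzes), "click_end")
    t_now <- t_return[i]
  }
  total_s <- t_now + params$post_dive_interval_s[n_dives]
  kt <- c(kt, total_s)
  kd <- c(kd, 0)

  t_s <- seq(0, total_s, by = 1 / sample_rate_hz)
  depth <- approx(kt, kd, xout = t_s, rule = 2)$y
  if (depth_noise_sd_m > 0) {
    depth <- depth + rnorm(length(depth), sd = depth_noise_sd_m)
  }
  ord <- order(audit_t)
  list(
    profile = tibble(t_s = t_s, depth_m = depth),
    audit = tibble(t_s = audit_t[ord], event = audit_kind[ord]),
    truth = dplyr::mutate(params,
                          dive_id = dplyr::row_number(),
                          t_leave_surface_s = t_leave,
                          t_return_surface_s = t_return)
  )
}
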