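# Synthetic satellite tracks: a smooth true movement path plus isotropic
# location error and occasional large outlier jumps, with ground-truth
# outlier flags retained for validating the speed filter.

#' Simulate a whale movement track as true positions
#'
#' A correlated random walk at a nominal ground speed, optionally pushed
#' away from and back towards a reference point during given windows to
#' emulate avoidance of an ensonified area and gradual return.
#'
#' @param start_time POSIXct start.
#' @param duration_h Track duration, hours.
#' @param fix_interval_h Time between fixes, hours.
#' @param start_lat,start_lon Starting position, decimal degrees.
#' @param speed_mps Mean ground speed, m/s.
#' @param heading_sd_rad Standard deviation of the per-step heading change.
#' @param seed Optional integer seed.
#' @return Tibble with `time`, `lat`, `lon`.
#' @export
simulate_whale_track <- function(start_time = as.POSIXct("2009-05-07 00:00:00",
                                                         tz = "UTC"),
                                 duration_h = 72, fix_interval_h = 2,
                                 start_lat = 24.5, start_lon = -77.5,
                                 speed_mps = 1.0, heading_sd_rad = 0.4,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration_h / fix_interval_h) + 1
  dt_s <- fix_interval_h * 3600
  heading <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 2, sd = heading_sd_rad)))
  step_km <- speed_mps * dt_s / 1000
  dx <- c(0, step_km * cos(heading))
  dy <- c(0, step_km * sin(heading))
  lat <- start_lat + cumsum(dy) / KM_PER_DEG
  lon <- start_lon + cumsum(dx) / (KM_PER_DEG * cos(start_lat * pi / 180))
  tibble(
    time = start_time + (seq_len(n) - 1) * dt_s,
    lat = lat,
    lon = lon
  )
}

#' Degrade a true track into Argos-like location fixes
#'
#' Adds isotropic Gaussian location error to every fix and replaces a
#' fraction of fixes with large jumps (of typical size `outlier_jump_km`)
#' that imply implausible swim speeds, emulating poor-quality satellite
#' locations. Ground-truth outlier flags are retained.
#'
#' @param true_track Tibble with `time`, `lat`, `lon`, time-ordered.
#' @param error_sd_km Isotropic location error standard deviation, km.
#' @param outlier_rate Fraction of fixes turned into outliers, in `[0, 1]`.
#' @param outlier_jump_km Displacement of outlier fixes, km.
#' @param seed Optional integer seed.
#' @return Tibble with `time`, `lat`, `lon`, `is_outlier`.
#' @export
simulate_argos_track <- function(true_track, error_sd_km = 0.5,
                                 outlier_rate = 0, outlier_jump_km = 100,
                                 seed = NULL) {
  assert_cols(true_track, c("time", "lat", "lon"))
  if (outlier_rate < 0 || outlier_rate > 1) {
    abort("`outlier_rate` must be in [0, 1].")
  }
  n <- nrow(true_track)
  if (n == 0) {
    return(tibble(time = true_track$time, lat = numeric(0),
                  lon = numeric(0), is_outlier = logical(0)))
  }
  if (is.unsorted(time_as_seconds(true_track$time))) {
    abort("`true_track` must be time-ordered.")
  }
  if (!is.null(seed)) set.seed(seed)
  coslat <- cos(true_track$lat * pi / 180)
  lat <- true_track$lat + rnorm(n, sd = error_sd_km) / KM_PER_DEG
  lon <- true_track$lon + rnorm(n, sd = error_sd_km) / (KM_PER_DEG * coslat)
  is_outlier <- rep(FALSE, n)
  if (outlier_rate > 0 && n > 1) {
    # non-adjacent outliers, so every flagged fix has a clean neighbour and
    # the implied approach speed is dominated by the jump
    cand <- sample(2:n)
    k <- integer(0)
    for (i in cand) {
      if (length(k) >= round(outlier_rate * n)) break
      if (!any(abs(k - i) == 1)) k <- c(k, i)
    }
    is_outlier[k] <- TRUE
    ang <- runif(length(k), 0, 2 * pi)
    lat[k] <- true_track$lat[k] + outlier_jump_km * sin(ang) / KM_PER_DEG
    lon[k] <- true_track$lon[k] +
      outlier_jump_km * cos(ang) / (KM_PER_DEG * coslat[k])
  }
  tibble(time = true_track$time, lat = lat, lon = lon,
         is_outlier = is_outlier)
}
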