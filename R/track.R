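# Satellite-track speed filtering and phase-wise distance summaries.
# Distances are great-circle on a sphere of radius 6371.0 km; the
# ellipsoidal error is below 0.5% at the scales involved.

track_distance_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

#' Filter satellite fixes by maximum plausible swim speed
#'
#' Iteratively removes the worst-offending fix until no pair of consecutive
#' retained fixes implies a speed above `vmax_mps`, in the spirit of
#' speed-based Argos track filters. At each step, among fixes involved in a
#' violating pair, the one with the largest root-mean-square speed to its
#' retained neighbours is discarded. The first fix is always retained.
#' Removed fixes are flagged, not deleted. With exactly two fixes there is
#' nothing to choose between, so both are retained (with a warning if the
#' pair violates the limit).
#'
#' @param fixes Tibble with `time` (POSIXct or numeric seconds), `lat`,
#'   `lon`. Duplicate timestamps are an error.
#' @param vmax_mps Maximum plausible sustained swim speed, m/s.
#' @return The input (sorted by time) with a logical `retained` column.
#' @export
speed_filter <- function(fixes, vmax_mps = 3.0) {
  assert_cols(fixes, c("time", "lat", "lon"))
  assert_scalar_number(vmax_mps, "vmax_mps", positive = TRUE)
  fixes <- dplyr::arrange(fixes, .data$time)
  tsec <- time_as_seconds(fixes$time)
  if (anyDuplicated(tsec)) abort("Duplicate timestamps in `fixes`.")
  n <- nrow(fixes)
  fixes$retained <- rep(TRUE, n)
  if (n < 2) return(fixes)
  if (n == 2) {
    v <- track_distance_m(fixes$lat[1], fixes$lon[1],
                          fixes$lat[2], fixes$lon[2]) / diff(tsec)
    if (v > vmax_mps) {
      warn("Two-fix track implies speed above `vmax_mps`; both fixes retained.")
    }
    return(fixes)
  }
  keep <- seq_len(n)
  repeat {
    la <- fixes$lat[keep]; lo <- fixes$lon[keep]; tt <- tsec[keep]
    v <- track_distance_m(la[-length(la)], lo[-length(lo)], la[-1], lo[-1]) /
      diff(tt)
    viol <- which(v > vmax_mps)
    if (length(viol) == 0 || length(keep) <= 2) break
    cand <- unique(c(viol, viol + 1))          # positions within `keep`
    cand <- cand[cand > 1]                     # first fix protected
    score <- vapply(cand, function(j) {
      vs <- c(if (j > 1) v[j - 1], if (j <= length(v)) v[j])
      sqrt(mean(vs^2))
    }, numeric(1))
    drop_j <- cand[order(-score, -cand)][1]
    keep <- keep[-drop_j]
  }
  fixes$retained <- seq_len(n) %in% keep
  fixes
}

#' Distance from each fix to a reference point
#'
#' Great-circle distance (sphere, R = 6371 km) from each location to a
#' reference point, by default the approximate centre of the monitored
#' range at 24.5 N, 77.5 W.
#'
#' @param fixes Tibble with `lat`, `lon`.
#' @param center_lat,center_lon Reference point, decimal degrees.
#' @return The input with a `dist_km` column added.
#' @examples
#' distance_to_center(tibble::tibble(lat = 25.5, lon = -77.5))$dist_km
#' @export
distance_to_center <- function(fixes, center_lat = 24.5, center_lon = -77.5) {
  assert_cols(fixes, c("lat", "lon"))
  dplyr::mutate(fixes, dist_km = track_distance_m(
    .data$lat, .data$lon, center_lat, center_lon
  ) / 1000)
}

#' Summarize distance to the range centre by exposure window
#'
#' Mean and sample standard deviation of the distance from each retained
#' fix to the range centre, per observation window. Fixes outside every
#' window are excluded; a window without fixes is reported with `n_fixes =
#' 0` and missing statistics.
#'
#' @param fixes Tibble with `time`, `lat`, `lon` and optionally `retained`
#'   (from [speed_filter()]); when present, only retained fixes are used.
#' @param windows Tibble with `window`, `start`, `end` (same time class as
#'   `fixes$time`).
#' @param center_lat,center_lon Passed to [distance_to_center()].
#' @return A tibble with `window`, `n_fixes`, `mean_km`, `sd_km`.
#' @export
phase_distance_summary <- function(fixes, windows,
                                   center_lat = 24.5, center_lon = -77.5) {
  assert_cols(fixes, c("time", "lat", "lon"))
  assert_cols(windows, c("window", "start", "end"))
  if (any(time_as_seconds(windows$end) <= time_as_seconds(windows$start))) {
    abort("Each window must have start < end.")
  }
  if ("retained" %in% names(fixes)) {
    fixes <- fixes[fixes$retained, , drop = FALSE]
  }
  fixes <- distance_to_center(fixes, center_lat, center_lon)
  tsec <- time_as_seconds(fixes$time)
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    sel <- tsec >= time_as_seconds(windows$start[i]) &
      tsec < time_as_seconds(windows$end[i])
    d <- fixes$dist_km[sel]
    tibble(
      window = windows$window[i],
      n_fixes = length(d),
      mean_km = if (length(d) > 0) mean(d) else NA_real_,
      sd_km = if (length(d) > 1) sd(d) else NA_real_
    )
  })
}

#' Plot a filtered track and its distance-to-centre series
#'
#' @param fixes Output of [speed_filter()] (rejected fixes drawn hollow).
#' @param center_lat,center_lon Reference point.
#' @return A ggplot object of distance to the range centre over time.
#' @export
plot_track_distance <- function(fixes, center_lat = 24.5,
                                center_lon = -77.5) {
  fixes <- distance_to_center(fixes, center_lat, center_lon)
  if (!"retained" %in% names(fixes)) fixes$retained <- TRUE
  ggplot2::ggplot(fixes, ggplot2::aes(x = .data$time, y = .data$dist_km,
                                      shape = .data$retained)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = NULL, y = "distance to range centre (km)",
                  shape = "retained") +
    ggplot2::theme_minimal()
}
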