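test_that("a steady track passes the speed filter untouched", {
  tr <- straight_track(12, speed_mps = 1)
  out <- speed_filter(tr)
  expect_true(all(out$retained))
})

test_that("a teleported fix is removed and only that fix", {
  tr <- straight_track(10, speed_mps = 1)
  bad <- 5
  tr$lat[bad] <- tr$lat[bad] + 1  # ~111 km jump in 1 h (~31 m/s)
  out <- speed_filter(tr)
  expect_equal(which(!out$retained), bad)
  # oracle: recomputed speeds of retained fixes all within the limit
  kept <- out[out$retained, ]
  d <- geosphere::distHaversine(cbind(kept$lon[-nrow(kept)],
                                      kept$lat[-nrow(kept)]),
                                cbind(kept$lon[-1], kept$lat[-1]),
                                r = 6371000)
  v <- d / as.numeric(diff(kept$time), units = "secs")
  expect_true(all(v <= 3))
})

test_that("two-fix tracks are retained regardless and duplicates rejected", {
  tr <- straight_track(2, speed_mps = 10)
  expect_warning(out <- speed_filter(tr), "both fixes retained")
  expect_true(all(out$retained))
  dup <- straight_track(3)
  dup$time[2] <- dup$time[1]
  expect_error(speed_filter(dup), "Duplicate")
})

test_that("speed filtering is idempotent", {
  tr <- simulate_whale_track(duration_h = 120, seed = 5)
  fx <- simulate_argos_track(tr, error_sd_km = 1, outlier_rate = 0.2,
                             seed = 6)
  once <- speed_filter(fx)
  again <- speed_filter(once[once$retained, c("time", "lat", "lon")])
  expect_true(all(again$retained))
})

test_that("distance to the range centre matches the haversine oracle", {
  expect_equal(distance_to_center(tibble::tibble(lat = 24.5,
                                                 lon = -77.5))$dist_km, 0)
  # 1 degree of latitude on a 6371-km sphere: R * pi/180
  d1 <- distance_to_center(tibble::tibble(lat = 25.5, lon = -77.5))$dist_km
  expect_lt(abs(d1 - 6371 * pi / 180), 0.1)
  # symmetry
  a <- tibble::tibble(lat = 25.1, lon = -77.9)
  d_ab <- distance_to_center(a, 24.5, -77.5)$dist_km
  d_ba <- distance_to_center(tibble::tibble(lat = 24.5, lon = -77.5),
                             25.1, -77.9)$dist_km
  expect_equal(d_ab, d_ba)
})

test_that("great-circle distance satisfies the triangle inequality", {
  set.seed(8)
  for (i in 1:50) {
    pts <- tibble::tibble(lat = runif(3, 23, 26), lon = runif(3, -79, -76))
    d <- function(i, j) {
      geosphere::distHaversine(c(pts$lon[i], pts$lat[i]),
                               c(pts$lon[j], pts$lat[j]), r = 6371000)
    }
    expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1)
  }
})

test_that("windowed distance summaries track an avoid-and-return pattern", {
  t0 <- as.POSIXct("2009-05-11 10:00:00", tz = "UTC")
  h <- 3600
  windows <- tibble::tibble(
    window = c("pre", "exposure", "post_0_72h", "post_72_144h"),
    start = t0 + c(-72, 0, 72, 144) * h,
    end = t0 + c(0, 72, 144, 216) * h
  )
  # piecewise track: near centre, far during exposure, returning after
  mk <- function(offset_h, dist_deg, n) {
    tibble::tibble(
      time = t0 + offset_h * h + seq_len(n) * 2 * h,
      lat = 24.5 + dist_deg, lon = -77.5
    )
  }
  fixes <- dplyr::bind_rows(
    mk(-72, 0.33, 30), mk(0, 0.60, 30), mk(72, 0.30, 30), mk(144, 0.12, 30)
  )
  s <- phase_distance_summary(fixes, windows)
  expect_equal(s$n_fixes, rep(30L, 4))
  expect_gt(s$mean_km[2], s$mean_km[1])
  expect_lt(s$mean_km[4], s$mean_km[3])
  expect_equal(s$sd_km, rep(0, 4))
})

test_that("empty and single-fix windows are reported as missing", {
  t0 <- as.POSIXct("2009-05-11 10:00:00", tz = "UTC")
  windows <- tibble::tibble(window = c("a", "b"),
                            start = c(t0, t0 + 3600),
                            end = c(t0 + 3600, t0 + 7200))
  fixes <- tibble::tibble(time = t0 + 30, lat = 25, lon = -77.5)
  s <- phase_distance_summary(fixes, windows)
  expect_equal(s$n_fixes, c(1L, 0L))
  expect_true(is.na(s$sd_km[1]))
  expect_true(is.na(s$mean_km[2]))
})

test_that("argos degradation honours its contract", {
  tr <- straight_track(50)
  same <- simulate_argos_track(tr, error_sd_km = 0, outlier_rate = 0)
  expect_equal(same$lat, tr$lat)
  expect_equal(same$lon, tr$lon)
  expect_error(simulate_argos_track(tr, outlier_rate = 1.5), "\\[0, 1\\]")
  empty <- simulate_argos_track(tr[0, ], 1)
  expect_equal(nrow(empty), 0)
  # flagged outliers all imply speeds above 3 m/s
  fx <- simulate_argos_track(tr, error_sd_km = 0, outlier_rate = 0.2,
                             outlier_jump_km = 100, seed = 9)
  d <- geosphere::distHaversine(cbind(fx$lon[-nrow(fx)], fx$lat[-nrow(fx)]),
                                cbind(fx$lon[-1], fx$lat[-1]), r = 6371000)
  v <- d / as.numeric(diff(fx$time), units = "secs")
  flagged <- which(fx$is_outlier)
  expect_true(all(v[flagged - 1] > 3))
})
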