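test_that("segmentation separates foraging dives from silent bounces", {
  # V-dive with clicks, then a shallow bounce without clicks
  fs <- 50
  t <- seq(0, 4000, by = 1 / fs)
  depth <- approx(c(0, 100, 110, 900, 1700, 1710, 2500, 2800, 3100, 4000),
                  c(0, 0, 2, 800, 2, 0, 0, 60, 0, 0), xout = t)$y
  audit <- tibble::tibble(t_s = c(800, 1000, 1600),
                          event = c("click_start", "buzz", "click_end"))
  dv <- segment_dives(tibble::tibble(t_s = t, depth_m = depth), audit)
  expect_equal(nrow(dv), 2)
  expect_equal(dv$is_deep_foraging, c(TRUE, FALSE))
  expect_lt(abs(dv$t_leave_surface_s[1] - 110), 0.5)
  expect_lt(abs(dv$t_return_surface_s[1] - 1700), 0.5)
})

test_that("definition arithmetic for ascent follows the last click", {
  # last click at 600 m, surfacing 1200 s later: ascent rate 0.5 m/s
  p <- dive_params(descent_rate_mps = 1.0, descent_duration_s = 800,
                   clicking_duration_s = 1500, n_buzzes = 10,
                   dive_depth_m = 900, ascent_rate_mps = 0.5,
                   silent_ascent_duration_s = 1200)
  sim <- simulate_dive_profile(p)
  dv <- segment_dives(sim$profile, sim$audit)
  est <- compute_dive_parameters(dv, sim$profile, sim$audit)
  expect_equal(est$ascent_rate_mps, 0.5, tolerance = 1e-3)
  expect_equal(est$silent_ascent_duration_s, 1200, tolerance = 0.02)
  expect_equal(est$buzz_rate_per_s * est$clicking_duration_s,
               as.numeric(est$n_buzzes), tolerance = 1e-9)
  # phase-duration bookkeeping
  expect_lte(est$descent_duration_s + est$clicking_duration_s +
               est$silent_ascent_duration_s,
             est$dive_duration_s + 1 / 50)
})

test_that("audit events outside every dive are an error", {
  p <- dive_params()
  sim <- simulate_dive_profile(p)
  bad_audit <- dplyr::bind_rows(sim$audit,
                                tibble::tibble(t_s = 1, event = "buzz"))
  dv <- segment_dives(sim$profile, sim$audit)
  expect_error(compute_dive_parameters(dv, sim$profile, bad_audit),
               "outside every dive")
})

test_that("non-monotone depth records are rejected", {
  prof <- tibble::tibble(t_s = c(0, 1, 1, 2), depth_m = 0)
  expect_error(segment_dives(prof, tibble::tibble(t_s = numeric(),
                                                  event = character())),
               "strictly increasing")
})

test_that("phase comparison summarizes identical groups identically", {
  p <- random_dive_params(4, seed = 12)
  tab <- dplyr::bind_rows(
    dplyr::mutate(p, label = "baseline"),
    dplyr::mutate(p, label = "exposure")
  )
  cmp <- phase_compare_table(tab)
  s <- tidy(cmp)
  wide <- tidyr::pivot_wider(s[, c("parameter", "label", "mean")],
                             names_from = "label", values_from = "mean")
  expect_equal(wide$baseline, wide$exposure)
})

test_that("a constructed ascent-rate effect falls outside the baseline bins", {
  base <- dplyr::mutate(random_dive_params(8, seed = 13), label = "baseline")
  expo <- dplyr::mutate(random_dive_params(2, seed = 14), label = "exposure")
  expo$ascent_rate_mps <- 0.1 * min(base$ascent_rate_mps)
  tab <- dplyr::bind_rows(base, expo)
  cmp <- phase_compare_table(tab)
  h <- cmp$histograms
  asc <- h[h$parameter == "ascent_rate_mps", ]
  # exposure dives occupy bins where no baseline dive falls
  occupied_e <- asc$bin_left[asc$label == "exposure" & asc$count > 0]
  occupied_b <- asc$bin_left[asc$label == "baseline" & asc$count > 0]
  expect_lt(max(occupied_e), min(occupied_b))
  expect_true(all(expo$ascent_rate_mps < min(base$ascent_rate_mps)))
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("single-dive groups reduce to the dive itself", {
  tab <- dplyr::bind_rows(
    dplyr::mutate(random_dive_params(1, seed = 15), label = "baseline"),
    dplyr::mutate(random_dive_params(1, seed = 16), label = "exposure")
  )
  s <- tidy(phase_compare_table(tab))
  one <- s[s$parameter == "dive_depth_m" & s$label == "baseline", ]
  expect_equal(one$mean, tab$dive_depth_m[tab$label == "baseline"])
  expect_true(is.na(one$sd))
})
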