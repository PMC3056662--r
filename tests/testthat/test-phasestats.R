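test_that("per-phase rate arithmetic matches hand-counted tables", {
  # 63 GCPs in 17 h -> 3.71/h; 265 in 43 h -> 6.16/h at 2-decimal display
  ph <- observation_phases(c("before", "post_recovery"),
                           c(0, 17) * 3600, c(17, 60) * 3600)
  gcps <- tibble::tibble(start_s = c(
    seq(0, 17 * 3600 - 1, length.out = 63),
    seq(17 * 3600, 60 * 3600 - 1, length.out = 265)
  ))
  s <- summarize_rates(gcps, ph)
  expect_equal(round(s$rate_per_h, 2), c(3.71, 6.16))
  # unrounded rates reproduce the integer counts exactly
  expect_equal(s$rate_per_h * s$duration_h, as.numeric(s$n_gcps))
})

test_that("phases without GCPs report zero rate and missing edge percent", {
  ph <- two_phases(1, 1)
  gcps <- tibble::tibble(start_s = c(100, 200), on_edge = c(TRUE, FALSE))
  s <- summarize_rates(gcps, ph)
  expect_equal(s$n_gcps, c(2L, 0L))
  expect_equal(s$rate_per_h, c(2, 0))
  expect_equal(s$pct_edge, c(50, NA))
})

test_that("malformed phase tables are rejected", {
  expect_error(observation_phases("a", 10, 10), "start_s < end_s")
  expect_error(observation_phases(c("a", "b"), c(0, 500), c(1000, 1500)),
               "overlap")
  ph <- two_phases(1, 1)
  expect_error(summarize_rates(tibble::tibble(start_s = 3 * 3600), ph),
               "outside every phase")
})

test_that("exhaustive randomization matches a brute-force placement oracle", {
  # 4 events, phases of 1 h and 2 h, grid step 0.1 h: oracle enumerates all
  # 30^4 placements directly
  ph <- two_phases(1, 2, names = c("a", "b"))
  gcps <- tibble::tibble(start_s = c(100, 200, 5000, 6000))
  rt <- randomization_test(gcps, ph, "a", "b", method = "exhaustive",
                           grid_step_h = 0.1)
  grid <- as.matrix(expand.grid(rep(list(1:30), 4)))
  ka <- rowSums(grid <= 10)
  stat_all <- ka / 1 - (4 - ka) / 2
  obs <- 2 / 1 - 2 / 2
  p_oracle <- mean(abs(stat_all) >= abs(obs) - 1e-9)
  expect_equal(rt$n_reps, 30^4)
  expect_lt(abs(rt$p_two_tailed - p_oracle), 1 / (rt$n_reps + 1))
})

test_that("identical rates in equal phases give p near 1", {
  ph <- two_phases(1, 1)
  gcps <- tibble::tibble(start_s = c(600, 1800, 3000, 4200, 5400, 6600))
  rt <- randomization_test(gcps, ph, "before", "during",
                           n_reps = 5000, seed = 4)
  expect_gt(rt$p_two_tailed, 0.9)
})

test_that("p-values are symmetric in the phase order and reproducible", {
  ph <- two_phases(2, 5)
  gcps <- simulate_phase_gcps(ph, c(4, 1.5), seed = 31)
  r1 <- randomization_test(gcps, ph, "before", "during", n_reps = 2e4,
                           seed = 7)
  r2 <- randomization_test(gcps, ph, "during", "before", n_reps = 2e4,
                           seed = 7)
  expect_equal(r1$p_two_tailed, r2$p_two_tailed)
  expect_equal(r1$observed_stat, -r2$observed_stat)
  r3 <- randomization_test(gcps, ph, "before", "during", n_reps = 2e4,
                           seed = 7)
  expect_identical(r1$p_two_tailed, r3$p_two_tailed)
})

test_that("a strong exposure-phase rate drop is detected", {
  # before-rate ~3.7/h dropping to ~1.1/h during exposure
  ph <- observation_phases(c("before", "during"),
                          c(0, 17) * 3600, c(17, 92) * 3600)
  gcps <- simulate_phase_gcps(ph, c(3.71, 1.09), seed = 5)
  expect_gte(nrow(gcps), 50)
  rt <- randomization_test(gcps, ph, "before", "during", n_reps = 1e5,
                           seed = 6)
  expect_lt(rt$p_two_tailed, 0.001)
})

test_that("add-one correction bounds the smallest attainable p", {
  ph <- two_phases(1, 10)
  gcps <- simulate_phase_gcps(ph, c(30, 0.5), seed = 8)
  rt <- randomization_test(gcps, ph, "before", "during", n_reps = 500,
                           seed = 9)
  expect_gte(rt$p_two_tailed, 1 / 501)
  expect_lte(rt$p_two_tailed, 1)
})

test_that("the standard hypothesis set runs over available phases", {
  ph <- observation_phases(
    c("before", "during", "recovery", "post_recovery"),
    c(0, 65, 133, 198) * 3600, c(65, 133, 198, 241) * 3600
  )
  gcps <- simulate_phase_gcps(ph, c(4.05, 1.37, 1.49, 6.16), seed = 10)
  res <- run_hypothesis_tests(gcps, ph, n_reps = 2000, seed = 11)
  expect_equal(res$hypothesis, paste0("H", 1:5))
  expect_true(all(res$p_two_tailed > 0 & res$p_two_tailed <= 1))
  # tidy/glance/autoplot surface
  rt <- randomization_test(gcps, ph, "before", "during", n_reps = 1000,
                           seed = 2)
  expect_s3_class(tidy(rt), "tbl_df")
  expect_equal(glance(rt)$hypothesis, "before vs during")
  expect_s3_class(autoplot(rt), "ggplot")
})
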