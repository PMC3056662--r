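test_that("band SPL recovers the level of an in-band tone", {
  # RMS 1e7 uPa <=> 140 dB re 1 uPa
  ps <- tone_series(140, freq_hz = 3500, dur_s = 1)
  ss <- band_spl(ps, c(3111, 3920))
  expect_lt(abs(max(ss$spl_db, na.rm = TRUE) - 140), 0.1)
})

test_that("silence yields missing SPL and out-of-band input is rejected", {
  ps <- pressure_series(rep(0, 16000), 16000)
  ss <- band_spl(ps, c(3111, 3920))
  expect_true(all(is.na(ss$spl_db)))
  expect_error(band_spl(ps, c(7000, 9000)), "Nyquist")
  expect_error(band_spl(ps, c(3111, 3920), window_s = 1e-4), "8 samples")
})

test_that("band filter rejects out-of-band energy strongly", {
  # tone one octave below the band: >= 40 dB down
  inband <- tone_series(140, 3500)
  below <- tone_series(140, 1750)
  s_in <- max(band_spl(inband, c(3111, 3920))$spl_db, na.rm = TRUE)
  s_out <- max(band_spl(below, c(3111, 3920))$spl_db, na.rm = TRUE)
  expect_gt(s_in - s_out, 40)
})

test_that("click rejection removes a short transient from the 200-ms level", {
  fs <- 16000
  t <- seq(0, 1, by = 1 / fs)
  tone <- sqrt(2) * 1e6 * sin(2 * pi * 3500 * t)  # 120 dB
  i <- round(0.5 * fs):(round(0.5 * fs) + round(0.005 * fs))
  hot <- tone
  hot[i] <- hot[i] * 10^(30 / 20)
  s_ref <- max(band_spl(pressure_series(tone, fs), c(3111, 3920))$spl_db,
               na.rm = TRUE)
  s_rej <- max(band_spl(pressure_series(hot, fs), c(3111, 3920),
                        click_reject = TRUE)$spl_db, na.rm = TRUE)
  s_raw <- max(band_spl(pressure_series(hot, fs), c(3111, 3920))$spl_db,
               na.rm = TRUE)
  expect_lt(abs(s_rej - s_ref), 0.5)
  expect_gt(s_raw, s_ref + 5)
})

test_that("third-octave band table enforces the 2^(1/3) ratio", {
  b <- third_octave_bands()
  expect_equal(nrow(b), 4)
  expect_equal(b$low_hz[1], 1960)
  expect_equal(b$high_hz[4], 4939)
  expect_error(third_octave_bands(c(1000, 3000)), "2\\^\\(1/3\\)")
})

test_that("max-over-band RL equals the active band and the pointwise max", {
  fs <- 16000
  # energy only in the 2467-3111 band
  ps <- tone_series(130, freq_hz = 2800, dur_s = 1, fs = fs)
  mx <- max_band_rl(ps, window_s = 0.2)
  one <- band_spl(ps, c(2467, 3111), window_s = 0.2)
  i <- which.max(one$spl_db)
  expect_lt(abs(mx$spl_db[i] - one$spl_db[i]), 1e-6)
  expect_equal(mx$band[i], "2467-3111")
  # pointwise-max oracle on a two-tone signal spanning two bands
  t <- seq(0, 1, by = 1 / fs)
  x <- sqrt(2) * 1e6 * (sin(2 * pi * 2200 * t) + sin(2 * pi * 4400 * t))
  ps2 <- pressure_series(x, fs)
  mx2 <- max_band_rl(ps2, window_s = 0.2)
  per <- purrr::pmap(third_octave_bands(), function(low_hz, high_hz) {
    band_spl(ps2, c(low_hz, high_hz), window_s = 0.2)$spl_db
  })
  oracle <- do.call(pmax, c(per, na.rm = TRUE))
  expect_equal(mx2$spl_db, oracle, tolerance = 1e-10)
})

test_that("ping SEL matches analytic energies", {
  fs <- 16000
  # 1.4-s constant tone at 130 dB inside a 2-s window padded with silence
  t <- seq(0, 1.4, by = 1 / fs)
  x <- c(rep(0, fs), sqrt(2) * upa_from_db(130) * sin(2 * pi * 3500 * t),
         rep(0, fs))
  ps <- pressure_series(x, fs)
  sel <- ping_sel(ps, 0.9, window_s = 2, band = c(3111, 3920))
  expect_lt(abs(sel - (130 + 10 * log10(1.4))), 0.1)
  # doubling pressure adds 20 log10(2) = 6.02 dB
  ps2 <- pressure_series(2 * x, fs)
  sel2 <- ping_sel(ps2, 0.9, window_s = 2, band = c(3111, 3920))
  expect_equal(sel2 - sel, 20 * log10(2), tolerance = 1e-9)
  expect_error(ping_sel(ps, 3.0, window_s = 2), "outside the record")
})

test_that("MFA-structured ping SEL matches direct numerical integration", {
  sched <- playback_schedule("MFA", n_pings = 1)
  sim <- simulate_playback_reception(sched, range_m = 1, noise_floor_db = 0,
                                     sample_rate_hz = 16000, seed = 1)
  fs <- 16000
  sel <- ping_sel(sim$series, 0, window_s = 2)
  # trapezoid-free oracle: direct sum of squared samples over the window
  w <- sim$series$samples[1:(2 * fs)]
  oracle <- 10 * log10(sum(w^2) / fs)
  expect_equal(sel, oracle, tolerance = 1e-9)
})

test_that("cumulative SEL follows energy addition", {
  expect_equal(cumulative_sel(120), 120)
  expect_equal(cumulative_sel(c(120, 120))[2], 120 + 10 * log10(2),
               tolerance = 1e-12)
  # +3 dB/ping ramp of 20 pings: total minus last in (2.9, 3.2) dB
  ramp <- 100 + 3 * (0:19)
  cum <- cumulative_sel(ramp)
  excess <- cum[20] - ramp[20]
  expect_gt(excess, 2.9)
  expect_lt(excess, 3.2)
  # permutation invariance of the final value; non-decreasing along any order
  perm <- sample(ramp)
  expect_equal(cumulative_sel(perm)[20], cum[20], tolerance = 1e-12)
  expect_true(all(diff(cumulative_sel(perm)) >= 0))
  expect_error(cumulative_sel(numeric(0)), "nonempty")
})

test_that("received-level prediction follows the spreading law", {
  # at the 1-m reference distance only the (negligible) absorption term
  # remains: 0.0002 dB at 0.2 dB/km
  expect_equal(predict_rl(212, 1), 212, tolerance = 1e-5)
  expect_equal(predict_rl(212, 1, transmission_loss_model(20, 0)), 212)
  expect_equal(predict_rl(212, 10000,
                          transmission_loss_model(20, 0.2)), 130)
  # strictly decreasing in range
  r <- sort(runif(50, 1, 30000))
  rl <- predict_rl(200, r)
  expect_true(all(diff(rl) < 0))
  expect_error(predict_rl(200, 0.5), ">= 1")
  expect_error(transmission_loss_model(-1, 0), ">= 0")
})

test_that("band SPL never exceeds broadband SPL", {
  set.seed(1)
  fs <- 16000
  x <- rnorm(fs, sd = 1e5)
  ps <- pressure_series(x, fs)
  broadband <- db_spl(sqrt(mean(x^2)))
  for (i in seq_len(nrow(third_octave_bands()))) {
    b <- unlist(third_octave_bands()[i, ])
    s <- band_spl(ps, b, window_s = 0.5)
    expect_lt(max(s$spl_db, na.rm = TRUE), broadband + 0.1)
  }
})
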