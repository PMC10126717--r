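test_that("default config matches the implanted six-channel roster", {
  cfg <- default_config()
  kinds <- vapply(cfg$channels, `[[`, "", "source_kind")
  expect_length(cfg$channels, 6)
  expect_equal(sum(kinds == "rpni"), 3)
  expect_equal(sum(kinds == "residual_muscle"), 3)
  expect_true(all(vapply(cfg$channels, `[[`, 0, "noise_floor_rms") == 1.43))
  # rest is silence on every channel
  expect_true(all(vapply(cfg$channels,
                         function(ch) ch$activation_gain[["rest"]], 0) == 0))
  # every grip has a distinct activation-gain vector
  g <- sapply(cfg$channels, function(ch) ch$activation_gain)
  grips <- setdiff(cfg$movements, "rest")
  for (i in seq_along(grips)[-1]) {
    for (j in seq_len(i - 1)) {
      expect_false(all(g[grips[i], ] == g[grips[j], ]))
    }
  }
})

test_that("rest recordings reproduce the configured noise floor RMS", {
  cfg <- grips_config()
  rec <- generate_trial("rest", 2, cfg, seed = 1)
  rms <- compute_rms(rec$samples)
  expect_true(all(abs(rms - 1.43) / 1.43 < 0.1))
  expect_true(all(rec$labels == "rest"))
})

test_that("plateau RMS follows variance additivity of carrier and noise", {
  ch <- channel_spec("ch1", "rpni", 1.43, c(rest = 0, fist = 100))
  cfg <- emg_config(list(ch), c("rest", "fist"), sample_rate = 1000)
  rec <- generate_trial("fist", 1, cfg, seed = 3)
  plateau <- rec$samples[1, 201:800] # between 200 ms rise and fall
  expect_lt(abs(compute_rms(plateau) - sqrt(100^2 + 1.43^2)) /
              sqrt(100^2 + 1.43^2), 0.1)
})

test_that("silent configuration produces all-zero samples", {
  ch <- channel_spec("ch1", "rpni", 0, c(rest = 0, fist = 0))
  cfg <- suppressWarnings(emg_config(list(ch), c("rest", "fist"),
                                     sample_rate = 1000))
  rec <- generate_trial("fist", 0.5, cfg, seed = 1)
  expect_true(all(rec$samples == 0))
})

test_that("unknown movement errors and names the channel", {
  cfg <- grips_config()
  expect_error(generate_trial("wiggle", 1, cfg, seed = 1), "median_rpni")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- grips_config()
  a <- generate_trial("pinch", 1, cfg, seed = 11, rest_pre = 0.2)
  b <- generate_trial("pinch", 1, cfg, seed = 11, rest_pre = 0.2)
  expect_identical(a$samples, b$samples)
  s1 <- generate_calibration_session(cfg, 2, session_spec(0, NULL, 5))
  s2 <- generate_calibration_session(cfg, 2, session_spec(0, NULL, 5))
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$trials, s2$trials)
})

test_that("every sample carries one label and trials partition the recording", {
  cfg <- grips_config()
  rec <- generate_calibration_session(cfg, 3, session_spec(0, NULL, 9))
  expect_length(rec$labels, ncol(rec$samples))
  tr <- rec$trials[order(rec$trials$start), ]
  expect_equal(tr$start[1], 0)
  expect_equal(tr$end[nrow(tr)], ncol(rec$samples))
  expect_true(all(tr$start[-1] == tr$end[-nrow(tr)]))
  # labelled movement samples sit inside the cued window of their trial
  for (k in seq_len(nrow(tr))) {
    seg <- rec$labels[(tr$start[k] + 1):tr$end[k]]
    expect_true(all(seg %in% c("rest", tr$movement[k])))
  }
})

test_that("carrier energy is confined to the 100-500 Hz band", {
  ch <- channel_spec("ch1", "rpni", 0, c(rest = 0, fist = 50))
  cfg <- suppressWarnings(emg_config(list(ch), c("rest", "fist")))
  rec <- generate_trial("fist", 10, cfg, seed = 2) # 30 kSps, pure carrier
  x <- rec$samples[1, 30001:270000] # steady plateau
  n <- length(x)
  p <- Mod(stats::fft(x))[seq_len(n / 2)]^2
  f <- (seq_len(n / 2) - 1) * 30000 / n
  inband <- sum(p[f >= 100 & f <= 500])
  outband <- sum(p[f < 100 | f > 500])
  expect_lt(outband, inband / 100) # >= 20 dB down
})

test_that("calibration sessions have reps x movements annotated trials", {
  cfg <- grips_config()
  rec <- generate_calibration_session(cfg, 5, session_spec(0, NULL, 2))
  expect_equal(nrow(rec$trials), 20)
  expect_equal(as.vector(table(rec$trials$movement)), rep(5, 4))
  one <- generate_calibration_session(cfg, 1, session_spec(0, NULL, 2),
                                      movements = "fist")
  expect_equal(nrow(one$trials), 1)
  expect_equal(one$trials$start, 0)
  expect_equal(one$trials$end, ncol(one$samples))
  expect_error(generate_calibration_session(cfg, 5, session_spec(0, NULL, 2),
                                            movements = character(0)))
})

test_that("longitudinal drift is reproducible, positive, and day-ordered", {
  cfg <- grips_config()
  flat <- generate_longitudinal_series(cfg, 4, drift_sigma = 0, seed = 3,
                                       recordings = FALSE)
  expect_true(all(vapply(flat, function(s) all(s$session$amplitude_scale == 1),
                         TRUE)))
  series <- generate_longitudinal_series(cfg, 16, drift_sigma = 0.5, seed = 3,
                                         recordings = FALSE)
  days <- vapply(series, function(s) s$session$day, 0)
  expect_length(days, 16)
  expect_true(all(diff(days) > 0))
  expect_equal(max(days), 604)
  scales <- vapply(series, function(s) s$session$amplitude_scale[[1]], 0)
  expect_true(all(scales > 0))
  expect_gt(stats::IQR(scales), 0)
  again <- generate_longitudinal_series(cfg, 16, drift_sigma = 0.5, seed = 3,
                                        recordings = FALSE)
  expect_identical(scales,
                   vapply(again, function(s) s$session$amplitude_scale[[1]], 0))
  # common mode shares one factor per session; per-channel mode does not
  expect_true(all(vapply(series, function(s) {
    length(unique(s$session$amplitude_scale)) == 1
  }, TRUE)))
  perch <- generate_longitudinal_series(cfg, 4, drift_sigma = 0.5,
                                        drift_mode = "per_channel", seed = 3,
                                        recordings = FALSE)
  expect_true(any(vapply(perch, function(s) {
    length(unique(s$session$amplitude_scale)) > 1
  }, TRUE)))
})

test_that("session drift rescales EMG but leaves the noise floor alone", {
  cfg <- grips_config()
  sc <- stats::setNames(rep(2, 6), channel_names(cfg))
  rec <- generate_trial("fist", 1, cfg, scale = sc, seed = 5, rest_pre = 1)
  rest <- rec$samples[, 1:1000]
  expect_true(all(abs(compute_rms(rest) - 1.43) / 1.43 < 0.1))
  plateau <- rec$samples[, 1201:1800]
  gains <- vapply(cfg$channels, function(ch) ch$activation_gain[["fist"]], 0)
  expected <- sqrt((2 * gains)^2 + 1.43^2)
  expect_true(all(abs(compute_rms(plateau) - expected) / expected < 0.15))
})
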