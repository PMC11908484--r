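test_that("bandpass filter suppresses out-of-band components, keeps passband", {
  fs <- 20000
  t <- seq(0, 1, by = 1 / fs)
  dc <- rep(2, length(t))
  out <- bandpass_filter(dc, fs)
  mid <- seq(2000, length(t) - 2000)
  expect_lt(max(abs(out[mid])), 1e-6 * 2)
  s1k <- sin(2 * pi * 1000 * t)
  g <- max(abs(bandpass_filter(s1k, fs)[mid]))
  expect_gte(g, 0.9); expect_lte(g, 1 + 1e-9)  # filtfilt round-off headroom
  s10 <- sin(2 * pi * 10 * t)
  expect_lt(max(abs(bandpass_filter(s10, fs)[mid])), 0.1)
  expect_error(
    bandpass_filter(s1k, fs, detection_config(band_high_hz = 11000)), "Nyquist")
})

test_that("noise estimate follows median(|x|)/0.6745", {
  expect_equal(estimate_noise(rep(3, 100)), 3 / 0.6745)
  expect_equal(estimate_noise(rep(0, 100)), 0)
  withr::with_seed(1, {
    expect_equal(estimate_noise(rnorm(1e6)), 1, tolerance = 0.01)
  })
  expect_error(estimate_noise(numeric(0)), "empty")
})

test_that("threshold detection fires on deflections, not noise", {
  withr::with_seed(2, {
    x <- rnorm(20000)
    x <- x / max(abs(x)) * 4.9 * estimate_noise(x)  # everything under 5 sigma
  })
  cfg <- detection_config()
  expect_length(detect_spikes(x, cfg, sigma_m = estimate_noise(x)), 0)

  withr::with_seed(3, x2 <- rnorm(20000))
  sm <- estimate_noise(x2)
  x2[10000:10003] <- -10 * sm
  ev <- detect_spikes(x2, cfg, sigma_m = sm)
  expect_length(ev, 1)
  expect_lt(abs(ev - 10000), 3)

  # dead time merges nearby events
  x3 <- rnorm(20000)
  sm3 <- estimate_noise(x3)
  x3[5000] <- -10 * sm3; x3[5005] <- -10 * sm3
  cfg40 <- detection_config(dead_time_samples = 40)
  expect_length(detect_spikes(x3, cfg40, sigma_m = sm3), 1)
})

test_that("extraction windows follow the 20-before/44-after layout", {
  x <- rnorm(2000)
  cfg <- detection_config(align_on = "threshold_crossing")
  ws <- extract_waveforms(x, 1000L, 20000, cfg, sigma_m = 1)
  expect_identical(dim(ws$waveforms), c(1L, 64L))
  expect_equal(ws$waveforms[1, ], x[980:1043])

  # minimum alignment recenters a lagged trough to index 20 (0-based)
  x4 <- rep(0, 2000)
  x4[1003] <- -5; x4[1002] <- -3; x4[1000] <- -2
  cfgm <- detection_config(align_on = "minimum")
  wsm <- extract_waveforms(x4, 1000L, 20000, cfgm, sigma_m = 0.1)
  expect_identical(which.min(wsm$waveforms[1, ]), 21L)

  # events too close to the edge are dropped and counted
  wse <- extract_waveforms(x, c(10L, 1000L), 20000, cfg, sigma_m = 1)
  expect_identical(nrow(wse$waveforms), 1L)
  expect_identical(wse$n_dropped, 1L)
})

test_that("normalization and gradient mapping match the hand-derived ramp", {
  dt <- 5e-5
  ramp <- matrix(0:63, 1, 64)
  ws <- waveform_set(ramp, times_ms = 0, dt_s = dt)
  ws <- normalize_and_gradient(ws)
  expect_identical(ncol(ws$features), 63L)
  expect_equal(as.numeric(ws$features), rep((1 / 63) / dt, 63))

  flat <- waveform_set(matrix(5, 2, 64), times_ms = c(0, 1), dt_s = dt)
  flat <- normalize_and_gradient(flat)
  expect_identical(flat$flat_rows, 1:2)
  expect_true(all(flat$features == 0))
})

test_that("normalization is idempotent and the gradient is affine-invariant", {
  withr::with_seed(4, W <- matrix(rnorm(50 * 64), 50))
  N1 <- minmax_rows(W)
  expect_equal(minmax_rows(N1), N1)
  ws_a <- normalize_and_gradient(waveform_set(W, seq_len(50)))
  ws_b <- normalize_and_gradient(waveform_set(3.7 * W + 11, seq_len(50)))
  expect_equal(ws_a$features, ws_b$features, tolerance = 1e-10)
})

test_that("detection round trip recovers simulated high-SNR spikes", {
  cfg <- sim_config(n_neurons = 3, duration_s = 10, noise_sigma = 3,
                    target_snr_range = c(4, 12), seed = 6)
  rec <- generate_recording(cfg)
  dc <- detection_config()
  filt <- bandpass_filter(rec$trace, cfg$sampling_rate_hz, dc)
  sm <- estimate_noise(filt)
  ev <- detect_spikes(filt, dc, sm)
  ws <- extract_waveforms(filt, ev, cfg$sampling_rate_hz, dc, sm)
  rec_recall <- detection_recall(ws$times_ms, rec$truth$spike_times_ms,
                                 rec$truth$snr, cfg$sampling_rate_hz,
                                 min_snr = 6, tol_samples = 2)
  expect_gte(rec_recall, 0.95)
})
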