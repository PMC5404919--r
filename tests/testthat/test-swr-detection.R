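test_that("detect_candidates finds bump apexes and merges close candidates", {
  fs <- 1000
  expect_equal(
    nrow(detect_candidates(lfp_recording(rep(0, fs), fs), swr_params())),
    0
  )

  # flat-ish background with one tall Gaussian bump: one candidate at apex
  set.seed(21)
  n <- 10 * fs
  base <- abs(1 + rnorm(n, sd = 0.02))
  t <- (0:(n - 1)) / fs
  bump <- function(c0, h, w = 0.01) h * exp(-(t - c0)^2 / (2 * w^2))
  one <- lfp_recording(base + bump(5, 1), fs)
  cand <- detect_candidates(lfp_recording(one$samples, fs), swr_params())
  expect_equal(nrow(cand), 1)
  expect_equal(cand$center_s, 5, tolerance = 0.001)

  # two bumps 30 ms apart merge into the larger one
  two <- lfp_recording(base + bump(5, 1) + bump(5.03, 1.5), fs)
  cand2 <- detect_candidates(two, swr_params())
  expect_equal(nrow(cand2), 1)
  expect_equal(cand2$center_s, 5.03, tolerance = 0.002)

  # bumps 200 ms apart stay separate
  far <- lfp_recording(base + bump(5, 1) + bump(5.2, 1.5), fs)
  expect_equal(nrow(detect_candidates(far, swr_params())), 2)
})

test_that("event_boundaries rejects windows without a supra-threshold excursion", {
  fs <- 10000
  set.seed(3)
  noise <- generate_lfp(synth_lfp_config(duration_s = 0.2,
                                         swr_rate_hz = 0, seed = 3))
  tf <- morlet_cwt(noise$recording, seq(100, 300, 2))
  # pure background: the center excursion criterion essentially never
  # brackets the window center
  b <- event_boundaries(tf, swr_params(boundary_threshold_sd = 50))
  expect_null(b)
})

test_that("measured amplitude is the peak-to-trough of the band-passed trace", {
  fs <- 10000
  a <- 7.5
  rec <- make_tone(200, fs, 0.2, amplitude = a)
  bp <- band_pass(rec, 150, 250)
  rms <- sliding_rms(bp, 5)
  tf <- morlet_cwt(rec, seq(100, 300, 2))
  bounds <- list(onset_s = 0.08, offset_s = 0.12)
  ev <- measure_event(bp, rms, tf, bounds, background = list(mean = 0, sd = 1))
  expect_equal(ev$amplitude_uv, 2 * a, tolerance = 0.05)
  expect_equal(ev$peak_freq_hz, 200, tolerance = 4)
  expect_error(
    measure_event(bp, rms, tf, list(onset_s = -1, offset_s = 0.1),
                  background = list(mean = 0, sd = 1)),
    "outside"
  )
})

test_that("noise-only windows measure below the RMS rejection threshold", {
  sim <- generate_lfp(synth_lfp_config(duration_s = 10, swr_rate_hz = 0,
                                       sampling_rate_hz = 10000, seed = 8))
  p <- swr_params()
  bp <- band_pass(sim$recording, 150, 250)
  rms <- sliding_rms(bp, p$rms_window_ms)
  bg <- list(mean = mean(rms$samples), sd = sd(rms$samples))
  win <- lfp_recording(sim$recording$samples[40001:42001], 10000,
                       start_time_s = 4)
  tf <- morlet_cwt(win, p$cwt_freqs_hz)
  ev <- measure_event(bp, rms, tf,
                      list(onset_s = 4.085, offset_s = 4.115), bg, p)
  expect_lt(ev$mean_rms_sd, 1.5)
})

test_that("rejection rules implement the duration and RMS criteria exactly", {
  ev <- data.frame(
    center_s = 1:3, onset_s = 0, offset_s = 1,
    duration_ms = c(9.9, 25, 25), peak_freq_hz = 200,
    amplitude_uv = 20, mean_rms_sd = c(5, 1.4, 2)
  )
  out <- apply_rejection(ev, swr_params())
  expect_equal(out$accepted, c(FALSE, FALSE, TRUE))
  expect_equal(out$reject_reason, c("short_duration", "low_rms", ""))
})

test_that("detect_swrs handles degenerate input and reports incidence as count/duration", {
  fs <- 10000
  zero <- lfp_recording(rep(0, fs * 2), fs)
  det <- detect_swrs(zero)
  expect_equal(det$summary$n_events, 0)
  expect_equal(det$summary$incidence_hz, 0)
  expect_true(is.na(det$summary$mean_peak_freq_hz))
  expect_error(detect_swrs(lfp_recording(rep(0, 100), fs)), "1 s")

  sim <- generate_lfp(synth_lfp_config(duration_s = 20, swr_rate_hz = 0.5,
                                       seed = 14))
  det2 <- detect_swrs(sim$recording)
  expect_equal(det2$summary$incidence_hz, det2$summary$n_events / 20)
  expect_true(all(det2$events$duration_ms[det2$events$accepted] >= 10))
  expect_true(all(det2$events$mean_rms_sd[det2$events$accepted] >= 1.5))
})

test_that("detection is equivariant under amplitude scaling", {
  sim <- generate_lfp(synth_lfp_config(duration_s = 20, swr_rate_hz = 0.4,
                                       seed = 15))
  det1 <- detect_swrs(sim$recording)
  scaled <- lfp_recording(sim$recording$samples * 3.2,
                          sim$recording$sampling_rate_hz)
  det2 <- detect_swrs(scaled)
  expect_equal(det2$events$center_s, det1$events$center_s, tolerance = 1e-9)
  expect_equal(det2$events$duration_ms, det1$events$duration_ms,
               tolerance = 1e-6)
  expect_equal(det2$events$peak_freq_hz, det1$events$peak_freq_hz)
  expect_equal(det2$events$amplitude_uv, 3.2 * det1$events$amplitude_uv,
               tolerance = 1e-6)
  expect_identical(det2$events$accepted, det1$events$accepted)
})

test_that("raising the detection threshold never increases accepted events", {
  sim <- generate_lfp(synth_lfp_config(duration_s = 20, swr_rate_hz = 0.5,
                                       seed = 16))
  counts <- sapply(c(3, 4, 5, 6), function(th) {
    detect_swrs(sim$recording,
                swr_params(detect_threshold_sd = th))$summary$n_events
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("high-SNR implanted ripples are recovered with correct frequency", {
  noise <- generate_lfp(synth_lfp_config(duration_s = 20, swr_rate_hz = 0,
                                         seed = 17))
  sigma_band <- sd(band_pass(noise$recording, 150, 250)$samples)
  cfg <- synth_lfp_config(duration_s = 20, swr_rate_hz = 0.5,
                          swr_freq_range_hz = c(199.99, 200.01),
                          swr_duration_ms = c(30, 0),
                          swr_amplitude_uv = c(8 * sigma_band, 0), seed = 17)
  sim <- generate_lfp(cfg)
  det <- detect_swrs(sim$recording)
  acc <- det$events[det$events$accepted, ]
  m <- match_ground_truth(acc, sim$events)
  expect_gte(m$sensitivity, 0.9)
  expect_lte(m$fdr, 0.1)
  expect_lte(m$freq_mae_hz, 5)
})
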