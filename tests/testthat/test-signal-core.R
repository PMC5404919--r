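test_that("band_pass passes the ripple band and rejects DC and low frequencies", {
  fs <- 2000
  dc <- lfp_recording(rep(5, fs * 2), fs)
  out <- band_pass(dc, 150, 250)
  expect_lt(max(abs(out$samples)), 0.01 * 5)

  tone200 <- make_tone(200, fs, 2)
  out200 <- band_pass(tone200, 150, 250)
  mid <- (fs %/% 2):(3 * fs %/% 2)  # interior, away from filter edges
  gain <- (max(out200$samples[mid]) - min(out200$samples[mid])) / 2
  expect_equal(gain, butter_bandpass_mag(200, 150, 250)^2, tolerance = 0.05)
  expect_gt(gain, 0.95)

  tone50 <- make_tone(50, fs, 2)
  out50 <- band_pass(tone50, 150, 250)
  atten_db <- -20 * log10(max(abs(out50$samples[mid])))
  expect_gt(atten_db, 20)
  # analytic oracle predicts far deeper rejection than the bound
  expect_lt(butter_bandpass_mag(50, 150, 250)^2, 10^(-20 / 20))
})

test_that("band_pass and high_pass validate their bands", {
  rec <- make_tone(10, 1000, 1)
  expect_error(band_pass(rec, 400, 600), "Nyquist")
  expect_error(band_pass(rec, 200, 100), "Nyquist")
  expect_error(high_pass(rec, 600), "Nyquist")
})

test_that("high_pass removes DC and passes high frequencies", {
  fs <- 2000
  out <- high_pass(lfp_recording(rep(3, fs), fs), 300)
  expect_lt(max(abs(out$samples)), 1e-6)

  tone500 <- make_tone(500, fs, 2)
  mid <- (fs %/% 2):(3 * fs %/% 2)
  g500 <- max(abs(high_pass(tone500, 300)$samples[mid]))
  expect_equal(g500, butter_highpass_mag(500, 300)^2, tolerance = 0.05)

  tone10 <- make_tone(10, fs, 2)
  g10 <- max(abs(high_pass(tone10, 300)$samples[mid]))
  expect_gt(-20 * log10(g10), 40)
})

test_that("filters are zero-phase and linear", {
  fs <- 2000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  # symmetric ripple-band packet: its filtered peak must not shift
  pulse <- exp(-(t - 1)^2 / (2 * 0.005^2)) * cos(2 * pi * 200 * (t - 1))
  rec <- lfp_recording(pulse, fs)
  out <- band_pass(rec, 150, 250)
  shift_ms <- abs(which.max(out$samples) - which.max(pulse)) / fs * 1000
  expect_lte(shift_ms, 1)

  scaled <- band_pass(lfp_recording(3.7 * pulse, fs), 150, 250)
  expect_equal(scaled$samples, 3.7 * out$samples, tolerance = 1e-8)
})

test_that("sliding_rms matches closed forms", {
  fs <- 1000
  const <- lfp_recording(rep(-2, fs), fs)
  expect_equal(sliding_rms(const, 5)$samples, rep(2, fs))

  tone <- make_tone(50, fs, 2)
  r <- sliding_rms(tone, 200)  # window of 10 periods
  mid <- (fs %/% 2):(3 * fs %/% 2)
  expect_equal(mean(r$samples[mid]), 1 / sqrt(2), tolerance = 0.01)

  zeros <- lfp_recording(rep(0, 100), fs)
  expect_equal(sliding_rms(zeros, 5)$samples, rep(0, 100))
  expect_error(sliding_rms(tone, -1), "positive")
  expect_error(sliding_rms(lfp_recording(rep(1, 10), fs), 1000), "shorter")
})

test_that("welch_spectrum localizes tones and satisfies Parseval", {
  fs <- 1000
  tone <- make_tone(35, fs, 20)
  ps <- welch_spectrum(tone, segment_s = 2)
  expect_equal(ps$freqs_hz[which.max(ps$power)], 35,
               tolerance = ps$resolution_hz)

  set.seed(11)
  noise <- lfp_recording(rnorm(fs * 30, sd = 2.5), fs)
  ps2 <- welch_spectrum(noise, segment_s = 2)
  integral <- sum(ps2$power) * ps2$resolution_hz
  expect_equal(integral, var(noise$samples), tolerance = 0.05 * var(noise$samples))

  zeros <- lfp_recording(rep(0, fs * 4), fs)
  expect_true(all(welch_spectrum(zeros)$power == 0))
  expect_error(welch_spectrum(make_tone(10, fs, 1), segment_s = 2), "shorter")
})

test_that("welch_spectrum is invariant to the recording start time", {
  set.seed(5)
  x <- rnorm(4000)
  a <- welch_spectrum(lfp_recording(x, 1000, start_time_s = 0))
  b <- welch_spectrum(lfp_recording(x, 1000, start_time_s = 123.4))
  expect_identical(a$power, b$power)
})

test_that("morlet_cwt localizes tones on the frequency grid", {
  fs <- 2000
  grid <- seq(100, 300, by = 2)
  for (f0 in c(120, 180, 240)) {
    tf <- morlet_cwt(make_tone(f0, fs, 1), grid)
    avg <- rowMeans(tf$power)
    expect_equal(tf$freqs_hz[which.max(avg)], f0, tolerance = 2)
  }
  zeros <- lfp_recording(rep(0, fs), fs)
  expect_true(all(morlet_cwt(zeros, grid)$power == 0))
  expect_error(morlet_cwt(make_tone(100, fs, 1), numeric(0)), "empty")
  expect_error(morlet_cwt(make_tone(100, fs, 1), c(100, 1500)), "Nyquist")
})

test_that("morlet_cwt resolves two tones and matches the direct convolution oracle", {
  fs <- 2000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 150 * t) + sin(2 * pi * 250 * t)
  rec <- lfp_recording(x, fs)
  grid <- seq(100, 300, by = 2)
  tf <- morlet_cwt(rec, grid)
  avg <- rowMeans(tf$power[, 400:1600])
  # local maxima of the time-averaged spectrum
  locmax <- which(diff(sign(diff(avg))) == -2) + 1
  peaks <- sort(grid[locmax][order(avg[locmax], decreasing = TRUE)][1:2])
  expect_true(all(abs(peaks - c(150, 250)) <= 2))

  xd <- x - mean(x)
  idx <- c(700, 1000, 1300)
  for (f0 in c(150, 200, 250)) {
    row <- which(grid == f0)
    oracle <- oracle_morlet_power(xd, fs, f0, 6, idx)
    expect_equal(tf$power[row, idx], oracle, tolerance = 1e-6)
  }
})

test_that("lfp_recording validates its inputs", {
  expect_error(lfp_recording(c(1, NA), 100), "non-finite")
  expect_error(lfp_recording(numeric(0), 100), "length")
  expect_error(lfp_recording(1:5, -1), "positive")
  rec <- lfp_recording(1:5, 10, start_time_s = 2)
  expect_equal(lfp_times(rec), 2 + (0:4) / 10)
  expect_equal(lfp_duration(rec), 0.5)
})
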