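#' @importFrom stats rnorm runif rexp
NULL

#' Configuration for the synthetic LFP generator
#'
#' Defines the study-like conditions emulated by [generate_lfp()]:
#' a 1/f^beta background, sharp-wave ripple packets (150-250 Hz
#' oscillations riding a slow sharp-wave deflection), an optional
#' continuous gamma oscillation, biphasic single-unit spikes and
#' high-amplitude hypersynchronous bursts.
#'
#' Ripple defaults follow reported in-vitro CA3 statistics: ~26.6 ms
#' mean duration and ~18 µV peak-to-trough amplitude (the envelope
#' amplitude parameter is half the peak-to-trough, default mean 9 µV),
#' frequencies spanning the 150-250 Hz ripple band, incidence around
#' 0.5 events/s.
#'
#' @param duration_s Recording duration in seconds (> 0).
#' @param sampling_rate_hz Sampling rate in Hz (default 10000).
#' @param noise_exponent Spectral slope beta of the background,
#'   power ~ 1/f^beta (default 1, pink noise).
#' @param noise_sd_uv Standard deviation of the background noise in µV.
#' @param swr_rate_hz Ripple event rate (events/s); Poisson gaps with a
#'   200 ms refractory period between centers.
#' @param swr_freq_range_hz Ripple carrier frequency range (low, high) Hz.
#' @param swr_duration_ms Ripple duration (mean, sd) in ms.
#' @param swr_amplitude_uv Ripple envelope peak amplitude (mean, sd) in
#'   µV; peak-to-trough of the implanted oscillation is twice this.
#' @param sharpwave_amplitude_uv Amplitude of the negative Gaussian
#'   sharp-wave deflection under each ripple (µV).
#' @param gamma_freq_hz Carrier frequency of the continuous gamma
#'   oscillation (Hz).
#' @param gamma_amplitude_uv Gamma amplitude in µV (default 0: gamma
#'   off, matching drug-free ripple recordings; carbachol-gamma
#'   simulations set it explicitly — 0.25 µV against the default 10 µV
#'   background reproduces normalized peak z-scores around 5, the
#'   healthy-tissue range).
#' @param burst_rate_hz Hypersynchronous-burst rate (events/s).
#' @param burst_amplitude_sd_multiples Burst peak amplitude as a multiple
#'   of the 300 Hz high-passed trace SD (default 12, above the 10 SD
#'   burst threshold).
#' @param unit_rate_hz Single-unit spike rate (events/s).
#' @param unit_amplitude_sd_multiples Unit peak amplitude as a multiple
#'   of the high-passed trace SD (default 5, inside the 3-10 SD unit
#'   tier).
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return An object of class `synth_lfp_config`.
#' @export
synth_lfp_config <- function(duration_s,
                             sampling_rate_hz = 10000,
                             noise_exponent = 1,
                             noise_sd_uv = 10,
                             swr_rate_hz = 0.5,
                             swr_freq_range_hz = c(150, 250),
                             swr_duration_ms = c(26.6, 4),
                             swr_amplitude_uv = c(9, 2),
                             sharpwave_amplitude_uv = 25,
                             gamma_freq_hz = 35,
                             gamma_amplitude_uv = 0,
                             burst_rate_hz = 0,
                             burst_amplitude_sd_multiples = 12,
                             unit_rate_hz = 0,
                             unit_amplitude_sd_multiples = 5,
                             seed = 1) {
  cfg <- list(
    duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
    noise_exponent = noise_exponent, noise_sd_uv = noise_sd_uv,
    swr_rate_hz = swr_rate_hz, swr_freq_range_hz = swr_freq_range_hz,
    swr_duration_ms = swr_duration_ms, swr_amplitude_uv = swr_amplitude_uv,
    sharpwave_amplitude_uv = sharpwave_amplitude_uv,
    gamma_freq_hz = gamma_freq_hz, gamma_amplitude_uv = gamma_amplitude_uv,
    burst_rate_hz = burst_rate_hz,
    burst_amplitude_sd_multiples = burst_amplitude_sd_multiples,
    unit_rate_hz = unit_rate_hz,
    unit_amplitude_sd_multiples = unit_amplitude_sd_multiples,
    seed = seed
  )
  validate_synth_lfp_config(cfg)
  structure(cfg, class = "synth_lfp_config")
}

validate_synth_lfp_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop(sprintf("%s: %s", field, msg), call. = FALSE)
  }
  chk(is.numeric(cfg$duration_s) && cfg$duration_s > 0,
      "duration_s", "must be > 0")
  chk(is.numeric(cfg$sampling_rate_hz) && cfg$sampling_rate_hz > 0,
      "sampling_rate_hz", "must be > 0")
  chk(is.numeric(cfg$noise_exponent) && cfg$noise_exponent >= 0,
      "noise_exponent", "must be >= 0")
  chk(is.numeric(cfg$noise_sd_uv) && cfg$noise_sd_uv >= 0,
      "noise_sd_uv", "must be >= 0")
  for (f in c("swr_rate_hz", "burst_rate_hz", "unit_rate_hz")) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0, f, "rate must be >= 0")
  }
  fr <- cfg$swr_freq_range_hz
  chk(length(fr) == 2 && fr[1] > 0 && fr[1] < fr[2] &&
        fr[2] < cfg$sampling_rate_hz / 2,
      "swr_freq_range_hz", "need 0 < low < high < Nyquist")
  chk(length(cfg$swr_duration_ms) == 2 && cfg$swr_duration_ms[1] > 0 &&
        cfg$swr_duration_ms[2] >= 0,
      "swr_duration_ms", "need (mean > 0, sd >= 0)")
  chk(length(cfg$swr_amplitude_uv) == 2 && cfg$swr_amplitude_uv[1] >= 0 &&
        cfg$swr_amplitude_uv[2] >= 0,
      "swr_amplitude_uv", "need (mean >= 0, sd >= 0)")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed", "must be a single integer")
  invisible(cfg)
}

# Seeded 1/f^beta Gaussian noise by FFT spectral shaping; returns a
# vector scaled to sd = noise_sd (the DC component is removed).
shaped_noise <- function(n, fs, beta, noise_sd) {
  if (noise_sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  shape <- c(0, f[-1]^(-beta / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
  x / stats::sd(x) * noise_sd
}

# Poisson event centers with a refractory gap, restricted to
# [margin, duration - margin].
poisson_centers <- function(rate_hz, duration_s, refractory_s, margin_s) {
  if (rate_hz <= 0) return(numeric(0))
  centers <- numeric(0)
  t <- margin_s
  repeat {
    t <- t + stats::rexp(1, rate_hz)
    if (t > duration_s - margin_s) break
    centers <- c(centers, t)
    t <- t + refractory_s
  }
  centers
}

new_gt <- function(kind, onset, offset, center, freq, amp) {
  data.frame(
    kind = kind, onset_s = onset, offset_s = offset, center_s = center,
    osc_freq_hz = freq, amplitude_uv = amp, stringsAsFactors = FALSE
  )
}

#' Generate a ground-truthed synthetic LFP recording
#'
#' Builds a 1/f^beta noise background and superposes the configured
#' events: sharp-wave ripples (carrier sinusoid under a Hann envelope of
#' the drawn duration plus a negative Gaussian sharp wave), an optional
#' continuous gamma oscillation, biphasic ~1 ms unit spikes and ~5 ms
#' high-frequency burst transients. Every implanted event is returned
#' with its ground-truth timing so detector performance can be scored.
#'
#' @param config A [synth_lfp_config()].
#' @return A list with elements `recording` (an [lfp_recording()]) and
#'   `events` (data frame sorted by onset with columns `kind`
#'   (`swr`/`gamma_epoch`/`unit`/`burst`), `onset_s`, `offset_s`,
#'   `center_s`, `osc_freq_hz`, `amplitude_uv`).
#' @export
#' @examples
#' sim <- generate_lfp(synth_lfp_config(duration_s = 10, seed = 42))
#' nrow(sim$events)
generate_lfp <- function(config) {
  if (!inherits(config, "synth_lfp_config")) {
    config <- do.call(synth_lfp_config, config)
  }
  validate_synth_lfp_config(config)
  set.seed(config$seed)
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  tvec <- (0:(n - 1)) / fs
  x <- shaped_noise(n, fs, config$noise_exponent, config$noise_sd_uv)
  gt <- list()

  # --- sharp-wave ripples -------------------------------------------------
  swr_centers <- poisson_centers(config$swr_rate_hz, config$duration_s,
                                 refractory_s = 0.2, margin_s = 0.15)
  for (c0 in swr_centers) {
    f0 <- stats::runif(1, config$swr_freq_range_hz[1],
                       config$swr_freq_range_hz[2])
    dur <- stats::rnorm(1, config$swr_duration_ms[1],
                        config$swr_duration_ms[2]) / 1000
    dur <- max(dur, 0.002)
    amp <- max(stats::rnorm(1, config$swr_amplitude_uv[1],
                            config$swr_amplitude_uv[2]), 0)
    onset <- c0 - dur / 2
    offset <- c0 + dur / 2
    i0 <- max(1L, floor(onset * fs) + 1L)
    i1 <- min(n, ceiling(offset * fs) + 1L)
    tt <- tvec[i0:i1]
    env <- 0.5 * (1 - cos(2 * pi * (tt - onset) / dur))
    env[tt < onset | tt > offset] <- 0
    ripple <- amp * env * cos(2 * pi * f0 * (tt - c0))
    x[i0:i1] <- x[i0:i1] + ripple
    # slow sharp-wave deflection under the ripple
    if (config$sharpwave_amplitude_uv != 0) {
      sig <- dur
      j0 <- max(1L, floor((c0 - 4 * sig) * fs) + 1L)
      j1 <- min(n, ceiling((c0 + 4 * sig) * fs) + 1L)
      ts <- tvec[j0:j1]
      x[j0:j1] <- x[j0:j1] -
        config$sharpwave_amplitude_uv * exp(-(ts - c0)^2 / (2 * sig^2))
    }
    gt[[length(gt) + 1]] <- new_gt("swr", onset, offset, c0, f0, amp)
  }

  # --- continuous gamma oscillation --------------------------------------
  if (config$gamma_amplitude_uv > 0) {
    x <- x + config$gamma_amplitude_uv * sin(2 * pi * config$gamma_freq_hz * tvec)
    gt[[length(gt) + 1]] <- new_gt(
      "gamma_epoch", 0, config$duration_s, config$duration_s / 2,
      config$gamma_freq_hz, config$gamma_amplitude_uv
    )
  }

  # --- units and bursts ---------------------------------------------------
  # Amplitudes are multiples of the high-passed (300 Hz) trace SD so the
  # 3 SD / 10 SD detector tiers are exercised directly.
  if (config$unit_rate_hz > 0 || config$burst_rate_hz > 0) {
    hp_cut <- min(300, fs / 2 * 0.9)
    base_rec <- lfp_recording(x, fs)
    sigma_hp <- stats::sd(high_pass(base_rec, hp_cut)$samples)
    if (sigma_hp == 0) sigma_hp <- 1
    # normalize each packet template by its post-high-pass peak, so the
    # configured multiple is expressed on the detector's amplitude scale
    hp_peak_ratio <- function(width_s, carrier_hz) {
      m <- max(64L, 8L * ceiling(width_s * fs))
      tt <- ((0:(m - 1)) - m / 2) / fs
      env <- 0.5 * (1 + cos(pi * pmin(abs(tt) / (width_s / 2), 1)))
      wf <- env * cos(2 * pi * carrier_hz * tt)
      wf <- wf / max(abs(wf))
      max(abs(high_pass(lfp_recording(wf, fs), hp_cut)$samples))
    }
    add_packet <- function(x, c0, width_s, carrier_hz, amp) {
      i0 <- max(1L, floor((c0 - width_s / 2) * fs) + 1L)
      i1 <- min(n, ceiling((c0 + width_s / 2) * fs) + 1L)
      tt <- tvec[i0:i1]
      env <- 0.5 * (1 - cos(2 * pi * (tt - (c0 - width_s / 2)) / width_s))
      env[tt < c0 - width_s / 2 | tt > c0 + width_s / 2] <- 0
      wf <- env * cos(2 * pi * carrier_hz * (tt - c0))
      if (max(abs(wf)) > 0) wf <- wf / max(abs(wf))
      x[i0:i1] <- x[i0:i1] + amp * wf
      x
    }
    unit_gain <- hp_peak_ratio(0.001, 1000)
    burst_gain <- hp_peak_ratio(0.005, 800)
    burst_centers <- poisson_centers(config$burst_rate_hz, config$duration_s,
                                     refractory_s = 0.05, margin_s = 0.05)
    unit_centers <- poisson_centers(config$unit_rate_hz, config$duration_s,
                                    refractory_s = 0.005, margin_s = 0.05)
    if (length(burst_centers)) {
      # keep unit spikes clear of bursts so tiers stay unambiguous
      near_burst <- vapply(unit_centers, function(c0) {
        any(abs(burst_centers - c0) < 0.01)
      }, logical(1))
      unit_centers <- unit_centers[!near_burst]
    }
    for (c0 in unit_centers) {
      amp <- config$unit_amplitude_sd_multiples * sigma_hp
      x <- add_packet(x, c0, 0.001, 1000, amp / unit_gain)
      gt[[length(gt) + 1]] <- new_gt("unit", c0 - 0.0005, c0 + 0.0005,
                                     c0, NA_real_, amp)
    }
    for (c0 in burst_centers) {
      amp <- config$burst_amplitude_sd_multiples * sigma_hp
      x <- add_packet(x, c0, 0.005, 800, amp / burst_gain)
      gt[[length(gt) + 1]] <- new_gt("burst", c0 - 0.0025, c0 + 0.0025,
                                     c0, NA_real_, amp)
    }
  }

  events <- if (length(gt)) do.call(rbind, gt) else
    new_gt(character(0), numeric(0), numeric(0), numeric(0),
           numeric(0), numeric(0))
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  list(recording = lfp_recording(x, fs), events = events)
}
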