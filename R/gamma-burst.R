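#' Gamma-oscillation and burst-detection parameters
#'
#' @param analysis_duration_s Length of recording used for the power
#'   spectrum (default 400 s).
#' @param norm_band_hz Normalization band (Hz): the 1/f-normalized
#'   spectrum is z-scored over this band (default 3-300 Hz).
#' @param gamma_band_hz Band searched for the gamma peak (default
#'   20-60 Hz, covering the 30-40 Hz carbachol gamma and its slowed
#'   variants).
#' @param hp_cutoff_hz High-pass cutoff revealing unit activity (Hz).
#' @param unit_threshold_sd Single-unit amplitude threshold in SDs of
#'   the high-passed trace.
#' @param burst_threshold_sd Hypersynchronous-burst threshold in SDs.
#' @param burst_refractory_ms Minimum spacing between bursts (ms).
#' @param welch_segment_s,welch_overlap Welch segmentation (default 2 s
#'   Hann segments, 50% overlap: 0.5 Hz resolution).
#' @return An object of class `gamma_params`.
#' @export
gamma_params <- function(analysis_duration_s = 400,
                         norm_band_hz = c(3, 300),
                         gamma_band_hz = c(20, 60),
                         hp_cutoff_hz = 300,
                         unit_threshold_sd = 3,
                         burst_threshold_sd = 10,
                         burst_refractory_ms = 20,
                         welch_segment_s = 2,
                         welch_overlap = 0.5) {
  stopifnot(unit_threshold_sd < burst_threshold_sd,
            norm_band_hz[1] > 0, norm_band_hz[1] < norm_band_hz[2])
  structure(
    list(
      analysis_duration_s = analysis_duration_s,
      norm_band_hz = norm_band_hz, gamma_band_hz = gamma_band_hz,
      hp_cutoff_hz = hp_cutoff_hz, unit_threshold_sd = unit_threshold_sd,
      burst_threshold_sd = burst_threshold_sd,
      burst_refractory_ms = burst_refractory_ms,
      welch_segment_s = welch_segment_s, welch_overlap = welch_overlap
    ),
    class = "gamma_params"
  )
}

#' 1/f-normalized, z-scored gamma power spectrum
#'
#' Welch spectrum of the unfiltered recording, whitened by multiplying
#' power by frequency (compensating the 1/f background), then z-scored
#' over the normalization band. The gamma peak is the frequency of
#' maximal z inside the gamma band; the band-mean z is also reported.
#'
#' @param rec An [lfp_recording()], at least `analysis_duration_s` long
#'   (the first `analysis_duration_s` seconds are used).
#' @param params A [gamma_params()].
#' @param allow_short Permit recordings shorter than
#'   `analysis_duration_s` (the whole recording is then used).
#' @return An object of class `gamma_spectrum`: `freqs_hz` (restricted
#'   to the normalization band), `power_raw` (µV²/Hz), `power_norm`
#'   (power x f), `power_z` (mean 0, SD 1 over the band),
#'   `peak_freq_hz`, `peak_power_z`, `gamma_band_mean_z`.
#' @export
#' @examples
#' cfg <- synth_lfp_config(duration_s = 30, sampling_rate_hz = 2000,
#'                         swr_rate_hz = 0, gamma_amplitude_uv = 20, seed = 1)
#' gs <- gamma_spectrum(generate_lfp(cfg)$recording, allow_short = TRUE)
#' gs$peak_freq_hz
gamma_spectrum <- function(rec, params = gamma_params(),
                           allow_short = FALSE) {
  stopifnot(inherits(rec, "lfp_recording"))
  dur <- lfp_duration(rec)
  if (dur < params$analysis_duration_s && !allow_short) {
    stop(sprintf(
      "recording (%.1f s) shorter than analysis_duration_s (%g s); use allow_short = TRUE to override",
      dur, params$analysis_duration_s
    ), call. = FALSE)
  }
  n_use <- min(length(rec$samples),
               round(params$analysis_duration_s * rec$sampling_rate_hz))
  use <- lfp_recording(rec$samples[1:n_use], rec$sampling_rate_hz,
                       rec$start_time_s)
  ps <- welch_spectrum(use, params$welch_segment_s, params$welch_overlap)
  keep <- ps$freqs_hz >= params$norm_band_hz[1] &
    ps$freqs_hz <= params$norm_band_hz[2]
  freqs <- ps$freqs_hz[keep]
  raw <- ps$power[keep]
  norm <- raw * freqs
  z <- (norm - mean(norm)) / stats::sd(norm)
  in_gamma <- freqs >= params$gamma_band_hz[1] &
    freqs <= params$gamma_band_hz[2]
  pk <- which(in_gamma)[which.max(z[in_gamma])]
  structure(
    list(
      freqs_hz = freqs, power_raw = raw, power_norm = norm, power_z = z,
      peak_freq_hz = freqs[pk], peak_power_z = z[pk],
      gamma_band_mean_z = mean(z[in_gamma]),
      resolution_hz = ps$resolution_hz
    ),
    class = "gamma_spectrum"
  )
}

#' Detect single units and hypersynchronous bursts
#'
#' Operates on the high-passed (default 300 Hz) trace. Excursions of
#' the absolute trace above `unit_threshold_sd` times the trace SD (the
#' RMS scale of the zero-mean high-passed signal) are events; those
#' whose peak reaches `burst_threshold_sd` SDs are hypersynchronous
#' bursts, the rest single units. Bursts closer than the refractory
#' period are merged keeping the larger peak. Thresholds are
#' SD-relative, so counts are invariant to trace scaling.
#'
#' @param rec An [lfp_recording()] of at least 1 s.
#' @param params A [gamma_params()].
#' @return An object of class `burst_report`: `unit_times_s`,
#'   `burst_times_s`, `unit_amplitudes_sd`, `burst_amplitudes_sd`,
#'   `unit_count`, `burst_count`, `burst_rate_hz`, `scale_uv` (the SD
#'   used as the amplitude scale).
#' @export
detect_units_bursts <- function(rec, params = gamma_params()) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (lfp_duration(rec) < 1) {
    stop("recording must be at least 1 s long", call. = FALSE)
  }
  fs <- rec$sampling_rate_hz
  hp <- high_pass(rec, params$hp_cutoff_hz)
  x <- abs(hp$samples)
  sigma <- stats::sd(hp$samples)
  if (sigma == 0) {
    return(structure(
      list(unit_times_s = numeric(0), burst_times_s = numeric(0),
           unit_amplitudes_sd = numeric(0), burst_amplitudes_sd = numeric(0),
           unit_count = 0L, burst_count = 0L, burst_rate_hz = 0,
           scale_uv = 0),
      class = "burst_report"
    ))
  }
  above <- x >= params$unit_threshold_sd * sigma
  if (!any(above)) {
    return(structure(
      list(unit_times_s = numeric(0), burst_times_s = numeric(0),
           unit_amplitudes_sd = numeric(0), burst_amplitudes_sd = numeric(0),
           unit_count = 0L, burst_count = 0L, burst_rate_hz = 0,
           scale_uv = sigma),
      class = "burst_report"
    ))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # bridge sub-millisecond gaps (zero crossings inside one biphasic spike)
  gap <- max(1L, round(0.001 * fs))
  ev_start <- integer(0); ev_end <- integer(0)
  for (k in runs) {
    if (length(ev_end) && starts[k] - ev_end[length(ev_end)] <= gap) {
      ev_end[length(ev_end)] <- ends[k]
    } else {
      ev_start <- c(ev_start, starts[k])
      ev_end <- c(ev_end, ends[k])
    }
  }
  peak_idx <- mapply(function(i0, i1) i0 + which.max(x[i0:i1]) - 1L,
                     ev_start, ev_end)
  peak_sd <- x[peak_idx] / sigma
  times <- hp$start_time_s + (peak_idx - 1) / fs
  is_burst <- peak_sd >= params$burst_threshold_sd
  bt <- times[is_burst]; bv <- peak_sd[is_burst]
  # deduplicate bursts by refractory period, keeping the larger peak
  if (length(bt) > 1) {
    refr <- params$burst_refractory_ms / 1000
    keep_t <- bt[1]; keep_v <- bv[1]
    for (j in 2:length(bt)) {
      if (bt[j] - keep_t[length(keep_t)] < refr) {
        if (bv[j] > keep_v[length(keep_v)]) {
          keep_t[length(keep_t)] <- bt[j]
          keep_v[length(keep_v)] <- bv[j]
        }
      } else {
        keep_t <- c(keep_t, bt[j])
        keep_v <- c(keep_v, bv[j])
      }
    }
    bt <- keep_t; bv <- keep_v
  }
  structure(
    list(
      unit_times_s = times[!is_burst],
      burst_times_s = bt,
      unit_amplitudes_sd = peak_sd[!is_burst],
      burst_amplitudes_sd = bv,
      unit_count = sum(!is_burst),
      burst_count = length(bt),
      burst_rate_hz = length(bt) / lfp_duration(rec),
      scale_uv = sigma
    ),
    class = "burst_report"
  )
}
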