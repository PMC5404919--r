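#' Sharp-wave ripple detection parameters
#'
#' Parameters of the ripple detector: detection happens on the sliding
#' RMS of the 150-250 Hz band-passed trace at 4 SDs above background;
#' event boundaries and peak frequency come from a Morlet wavelet
#' transform of the unfiltered trace in a 200 ms window around each
#' candidate, with the boundary threshold 2 SDs above baseline power
#' (baseline taken from the window's first 50 ms at 250 Hz); events
#' shorter than 10 ms or with mean RMS below 1.5 SDs above background
#' are rejected.
#'
#' @param band_hz Ripple band (low, high) in Hz.
#' @param detect_threshold_sd RMS detection threshold in SDs above the
#'   background mean.
#' @param window_halfwidth_ms Half-width of the wavelet analysis window
#'   around each candidate center (ms).
#' @param boundary_threshold_sd Boundary threshold in SDs above baseline
#'   wavelet power.
#' @param baseline_window_ms Length of the baseline segment at the start
#'   of the analysis window (ms).
#' @param baseline_freq_hz Frequency at which baseline power statistics
#'   are taken (Hz).
#' @param rms_reject_sd Events with mean RMS (in SDs above background)
#'   below this are rejected.
#' @param min_duration_ms Events shorter than this are rejected (ms).
#' @param rms_window_ms Sliding RMS window (ms).
#' @param min_center_separation_ms Candidates closer than this are merged
#'   keeping the larger RMS peak (ms).
#' @param cwt_freqs_hz Wavelet analysis frequency grid (Hz).
#' @param omega0 Morlet wavelet parameter.
#' @param background Background statistic for the RMS trace: `"moments"`
#'   (mean/SD over the whole recording) or `"robust"`
#'   (median / 1.4826 MAD).
#' @param boundary_power Power trace used for boundary crossings:
#'   `"band_mean"` (mean wavelet power over the ripple band, default),
#'   `"baseline_freq"` (power at `baseline_freq_hz` only) or
#'   `"peak_freq"` (power at the window's peak frequency).
#' @return An object of class `swr_params`.
#' @export
swr_params <- function(band_hz = c(150, 250),
                       detect_threshold_sd = 4,
                       window_halfwidth_ms = 100,
                       boundary_threshold_sd = 2,
                       baseline_window_ms = 50,
                       baseline_freq_hz = 250,
                       rms_reject_sd = 1.5,
                       min_duration_ms = 10,
                       rms_window_ms = 5,
                       min_center_separation_ms = 50,
                       cwt_freqs_hz = seq(100, 300, by = 2),
                       omega0 = 6,
                       background = c("moments", "robust"),
                       boundary_power = c("band_mean", "baseline_freq",
                                          "peak_freq")) {
  p <- list(
    band_hz = band_hz, detect_threshold_sd = detect_threshold_sd,
    window_halfwidth_ms = window_halfwidth_ms,
    boundary_threshold_sd = boundary_threshold_sd,
    baseline_window_ms = baseline_window_ms,
    baseline_freq_hz = baseline_freq_hz,
    rms_reject_sd = rms_reject_sd, min_duration_ms = min_duration_ms,
    rms_window_ms = rms_window_ms,
    min_center_separation_ms = min_center_separation_ms,
    cwt_freqs_hz = cwt_freqs_hz, omega0 = omega0,
    background = match.arg(background),
    boundary_power = match.arg(boundary_power)
  )
  stopifnot(
    p$detect_threshold_sd > 0, p$boundary_threshold_sd > 0,
    p$rms_reject_sd > 0, p$min_duration_ms > 0,
    p$min_duration_ms < 2 * p$window_halfwidth_ms,
    p$band_hz[1] >= min(p$cwt_freqs_hz), p$band_hz[2] <= max(p$cwt_freqs_hz)
  )
  structure(p, class = "swr_params")
}

# Background statistics (mean, sd) of the RMS trace.
rms_background <- function(rms_samples, method) {
  if (method == "robust") {
    m <- stats::median(rms_samples)
    s <- stats::mad(rms_samples, constant = 1.4826)
  } else {
    m <- mean(rms_samples)
    s <- stats::sd(rms_samples)
  }
  list(mean = m, sd = s)
}

#' Detect candidate ripple centers on the RMS envelope
#'
#' Finds excursions of the RMS trace above
#' `background mean + detect_threshold_sd * SD`; each excursion yields
#' one candidate at the local maximum of the RMS nearest the threshold
#' crossing (the excursion apex). Candidates closer than
#' `min_center_separation_ms` are merged, keeping the larger peak.
#'
#' @param rms An [lfp_recording()] holding the sliding RMS of the
#'   band-passed trace.
#' @param params An [swr_params()].
#' @param background Optional list `(mean, sd)` of precomputed background
#'   statistics; computed from `rms` if omitted.
#' @return A data frame with `center_s` and `rms_peak` per candidate.
#' @export
detect_candidates <- function(rms, params = swr_params(), background = NULL) {
  stopifnot(inherits(rms, "lfp_recording"))
  fs <- rms$sampling_rate_hz
  n <- length(rms$samples)
  if (n < round(params$rms_window_ms / 1000 * fs)) {
    stop("rms trace shorter than one RMS window", call. = FALSE)
  }
  if (is.null(background)) {
    background <- rms_background(rms$samples, params$background)
  }
  thr <- background$mean + params$detect_threshold_sd * background$sd
  above <- rms$samples > thr
  if (!any(above)) {
    return(data.frame(center_s = numeric(0), rms_peak = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peaks_idx <- vapply(runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    i0 + which.max(rms$samples[i0:i1]) - 1L
  }, integer(1))
  peaks_val <- rms$samples[peaks_idx]
  # merge candidates closer than the separation limit, keep larger peak
  min_gap <- params$min_center_separation_ms / 1000 * fs
  ord <- order(peaks_idx)
  peaks_idx <- peaks_idx[ord]; peaks_val <- peaks_val[ord]
  keep_idx <- integer(0); keep_val <- numeric(0)
  for (j in seq_along(peaks_idx)) {
    if (length(keep_idx) && peaks_idx[j] - keep_idx[length(keep_idx)] < min_gap) {
      if (peaks_val[j] > keep_val[length(keep_val)]) {
        keep_idx[length(keep_idx)] <- peaks_idx[j]
        keep_val[length(keep_val)] <- peaks_val[j]
      }
    } else {
      keep_idx <- c(keep_idx, peaks_idx[j])
      keep_val <- c(keep_val, peaks_val[j])
    }
  }
  data.frame(
    center_s = rms$start_time_s + (keep_idx - 1) / fs,
    rms_peak = keep_val
  )
}

#' Ripple boundaries from a wavelet transform window
#'
#' Baseline power statistics come from the first `baseline_window_ms`
#' of the window at `baseline_freq_hz`; boundaries are the edges of the
#' supra-threshold excursion of the boundary power trace (by default the
#' ripple-band mean power) containing the window center, where the
#' threshold is `baseline mean + boundary_threshold_sd * SD`. If the
#' center lies in no excursion, the candidate is rejected.
#'
#' @param tf A `tf_power` object spanning the analysis window.
#' @param params An [swr_params()].
#' @return A list `(onset_s, offset_s)` or `NULL` when no boundary
#'   crossing brackets the window center.
#' @export
event_boundaries <- function(tf, params = swr_params()) {
  stopifnot(inherits(tf, "tf_power"))
  nt <- ncol(tf$power)
  dt <- tf$times_s[2] - tf$times_s[1]
  fs <- 1 / dt
  nb <- min(nt, round(params$baseline_window_ms / 1000 * fs))
  b_row <- which.min(abs(tf$freqs_hz - params$baseline_freq_hz))
  base <- tf$power[b_row, 1:nb]
  mu_b <- mean(base)
  sd_b <- stats::sd(base)
  band_rows <- tf$freqs_hz >= params$band_hz[1] &
    tf$freqs_hz <= params$band_hz[2]
  p_t <- switch(params$boundary_power,
    band_mean = colMeans(tf$power[band_rows, , drop = FALSE]),
    baseline_freq = tf$power[b_row, ],
    peak_freq = {
      pk <- which.max(rowMeans(tf$power[band_rows, , drop = FALSE]))
      tf$power[which(band_rows)[pk], ]
    }
  )
  thr <- mu_b + params$boundary_threshold_sd * sd_b
  above <- p_t > thr
  center <- ceiling(nt / 2)
  # allow the excursion to sit within a half RMS window of the center
  slack <- max(1L, round(params$rms_window_ms / 2 / 1000 * fs))
  probe <- max(1L, center - slack):min(nt, center + slack)
  hit <- probe[above[probe]]
  if (!length(hit)) return(NULL)
  i <- hit[which.max(p_t[hit])]
  i0 <- i
  while (i0 > 1L && above[i0 - 1L]) i0 <- i0 - 1L
  i1 <- i
  while (i1 < nt && above[i1 + 1L]) i1 <- i1 + 1L
  list(onset_s = tf$times_s[i0], offset_s = tf$times_s[i1])
}

#' Measure a detected ripple within its boundaries
#'
#' Peak frequency is the analysis frequency with maximal time-averaged
#' wavelet power inside the boundaries (ties broken toward the lower
#' frequency); amplitude is the peak-to-trough of the band-passed trace
#' inside the boundaries; `mean_rms_sd` is the boundary-average of the
#' RMS trace expressed in SDs above the background mean.
#'
#' @param bp Band-passed [lfp_recording()] (whole recording).
#' @param rms Sliding-RMS [lfp_recording()] (whole recording).
#' @param tf `tf_power` for the analysis window.
#' @param bounds List `(onset_s, offset_s)` from [event_boundaries()].
#' @param background List `(mean, sd)` of the RMS background.
#' @param params An [swr_params()].
#' @return One-row data frame with `center_s`, `onset_s`, `offset_s`,
#'   `duration_ms`, `peak_freq_hz`, `amplitude_uv`, `mean_rms_sd`.
#' @export
measure_event <- function(bp, rms, tf, bounds, background,
                          params = swr_params()) {
  if (bounds$onset_s < tf$times_s[1] - 1e-9 ||
      bounds$offset_s > tf$times_s[length(tf$times_s)] + 1e-9) {
    stop("bounds: boundaries lie outside the analysis window", call. = FALSE)
  }
  cols <- tf$times_s >= bounds$onset_s & tf$times_s <= bounds$offset_s
  avg_pow <- rowMeans(tf$power[, cols, drop = FALSE])
  peak_freq <- tf$freqs_hz[which.max(avg_pow)]  # which.max -> lowest tie
  fs <- bp$sampling_rate_hz
  j0 <- max(1L, round((bounds$onset_s - bp$start_time_s) * fs) + 1L)
  j1 <- min(length(bp$samples),
            round((bounds$offset_s - bp$start_time_s) * fs) + 1L)
  seg <- bp$samples[j0:j1]
  amplitude <- max(seg) - min(seg)
  rms_seg <- rms$samples[j0:j1]
  mean_rms_sd <- mean((rms_seg - background$mean) / background$sd)
  data.frame(
    center_s = (bounds$onset_s + bounds$offset_s) / 2,
    onset_s = bounds$onset_s, offset_s = bounds$offset_s,
    duration_ms = (bounds$offset_s - bounds$onset_s) * 1000,
    peak_freq_hz = peak_freq, amplitude_uv = amplitude,
    mean_rms_sd = mean_rms_sd
  )
}

#' Apply the duration and RMS rejection rules
#'
#' Keeps events with `duration_ms >= min_duration_ms` (rejecting
#' single-unit contamination) and `mean_rms_sd >= rms_reject_sd`;
#' order is preserved and rejected events are annotated, not dropped.
#'
#' @param events Data frame of measured events ([measure_event()] rows).
#' @param params An [swr_params()].
#' @return The events data frame with logical `accepted` and character
#'   `reject_reason` (`""`, `"short_duration"` or `"low_rms"`; the
#'   duration rule is reported first when both fail).
#' @export
apply_rejection <- function(events, params = swr_params()) {
  if (nrow(events) == 0) {
    events$accepted <- logical(0)
    events$reject_reason <- character(0)
    return(events)
  }
  short <- events$duration_ms < params$min_duration_ms
  weak <- events$mean_rms_sd < params$rms_reject_sd
  events$accepted <- !short & !weak
  events$reject_reason <- ifelse(short, "short_duration",
                                 ifelse(weak, "low_rms", ""))
  events
}

#' Detect sharp-wave ripples in a recording
#'
#' Full pipeline: band-pass (150-250 Hz) -> sliding RMS -> threshold
#' candidates -> per-candidate Morlet wavelet window -> boundary and
#' peak-frequency estimation -> amplitude/RMS measurement -> rejection
#' rules -> summary. Candidates whose 200 ms analysis window would
#' extend past the recording, or with no boundary crossing, are
#' discarded and counted in the QC log.
#'
#' @param rec An [lfp_recording()] of at least 1 s.
#' @param params An [swr_params()].
#' @return A list with `events` (data frame: `id`, `center_s`,
#'   `onset_s`, `offset_s`, `duration_ms`, `peak_freq_hz`,
#'   `amplitude_uv`, `mean_rms_sd`, `accepted`, `reject_reason`),
#'   `summary` (see [swr_summary()]) and `qc`
#'   (`n_candidates`, `n_edge_discarded`, `n_no_boundary`).
#' @export
#' @examples
#' sim <- generate_lfp(synth_lfp_config(duration_s = 20, seed = 3))
#' det <- detect_swrs(sim$recording)
#' det$summary$incidence_hz
detect_swrs <- function(rec, params = swr_params()) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (lfp_duration(rec) < 1) {
    stop("recording must be at least 1 s long", call. = FALSE)
  }
  fs <- rec$sampling_rate_hz
  bp <- band_pass(rec, params$band_hz[1], params$band_hz[2])
  rms <- sliding_rms(bp, params$rms_window_ms)
  background <- rms_background(rms$samples, params$background)
  cands <- detect_candidates(rms, params, background)
  half <- round(params$window_halfwidth_ms / 1000 * fs)
  n <- length(rec$samples)
  rows <- list()
  n_edge <- 0L
  n_nobound <- 0L
  for (k in seq_len(nrow(cands))) {
    ci <- round((cands$center_s[k] - rec$start_time_s) * fs) + 1L
    if (ci - half < 1L || ci + half > n) {
      n_edge <- n_edge + 1L
      next
    }
    win <- lfp_recording(rec$samples[(ci - half):(ci + half)], fs,
                         start_time_s = rec$start_time_s + (ci - half - 1) / fs)
    tf <- morlet_cwt(win, params$cwt_freqs_hz, params$omega0)
    bounds <- event_boundaries(tf, params)
    if (is.null(bounds)) {
      n_nobound <- n_nobound + 1L
      next
    }
    rows[[length(rows) + 1]] <-
      measure_event(bp, rms, tf, bounds, background, params)
  }
  events <- if (length(rows)) do.call(rbind, rows) else data.frame(
    center_s = numeric(0), onset_s = numeric(0), offset_s = numeric(0),
    duration_ms = numeric(0), peak_freq_hz = numeric(0),
    amplitude_uv = numeric(0), mean_rms_sd = numeric(0)
  )
  events <- apply_rejection(events, params)
  events <- cbind(id = seq_len(nrow(events)), events)
  rownames(events) <- NULL
  list(
    events = events,
    summary = swr_summary(events, lfp_duration(rec)),
    qc = list(n_candidates = nrow(cands), n_edge_discarded = n_edge,
              n_no_boundary = n_nobound)
  )
}

#' Per-recording ripple summary
#'
#' @param events Event data frame with an `accepted` column.
#' @param duration_s Analyzed recording duration in seconds.
#' @return List with `n_events`, `incidence_hz`
#'   (`n_events / duration_s`) and mean peak frequency, amplitude and
#'   duration over accepted events (`NA` when there are none).
#' @export
swr_summary <- function(events, duration_s) {
  acc <- events[events$accepted, , drop = FALSE]
  n <- nrow(acc)
  list(
    n_events = n,
    duration_s = duration_s,
    incidence_hz = n / duration_s,
    mean_peak_freq_hz = if (n) mean(acc$peak_freq_hz) else NA_real_,
    mean_amplitude_uv = if (n) mean(acc$amplitude_uv) else NA_real_,
    mean_duration_ms = if (n) mean(acc$duration_ms) else NA_real_
  )
}

#' Score detections against ground truth
#'
#' Greedy one-to-one matching of accepted detections to implanted events
#' by increasing center distance, within a tolerance.
#'
#' @param detected Data frame of accepted events (needs `center_s`;
#'   `peak_freq_hz`/`duration_ms` used when present).
#' @param truth Ground-truth data frame (needs `center_s`; `osc_freq_hz`,
#'   `onset_s`/`offset_s` used when present).
#' @param tol_s Maximal center distance for a match (default 0.02 s).
#' @return List with `n_truth`, `n_detected`, `n_matched`, `sensitivity`,
#'   `fdr`, and mean absolute errors `freq_mae_hz` and `duration_mae_ms`
#'   over matches (`NA` when unavailable).
#' @export
match_ground_truth <- function(detected, truth, tol_s = 0.02) {
  nd <- nrow(detected)
  nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(n_truth = nt, n_detected = nd, n_matched = 0L,
                sensitivity = if (nt) 0 else NA_real_,
                fdr = if (nd) 1 else NA_real_,
                freq_mae_hz = NA_real_, duration_mae_ms = NA_real_))
  }
  d <- abs(outer(detected$center_s, truth$center_s, "-"))
  pairs <- which(d <= tol_s, arr.ind = TRUE)
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_d <- logical(nd)
  used_t <- logical(nt)
  match_d <- integer(0)
  match_t <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- used_t[j] <- TRUE
      match_d <- c(match_d, i)
      match_t <- c(match_t, j)
    }
  }
  m <- length(match_d)
  freq_mae <- if (m && !is.null(detected$peak_freq_hz) &&
                  !is.null(truth$osc_freq_hz)) {
    mean(abs(detected$peak_freq_hz[match_d] - truth$osc_freq_hz[match_t]))
  } else NA_real_
  dur_mae <- if (m && !is.null(detected$duration_ms) &&
                 !is.null(truth$onset_s)) {
    mean(abs(detected$duration_ms[match_d] -
               (truth$offset_s[match_t] - truth$onset_s[match_t]) * 1000))
  } else NA_real_
  list(
    n_truth = nt, n_detected = nd, n_matched = m,
    sensitivity = m / nt, fdr = (nd - m) / nd,
    freq_mae_hz = freq_mae, duration_mae_ms = dur_mae
  )
}
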