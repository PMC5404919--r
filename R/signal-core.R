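#' @importFrom signal butter filtfilt
#' @importFrom stats fft sd
NULL

check_band <- function(low_hz, high_hz, fs) {
  if (!is.finite(low_hz) || !is.finite(high_hz) || low_hz <= 0 ||
      high_hz <= low_hz || high_hz >= fs / 2) {
    stop(sprintf(
      "band (%g, %g) Hz: need 0 < low < high < Nyquist (%g Hz)",
      low_hz, high_hz, fs / 2
    ), call. = FALSE)
  }
}

# Forward-backward filtering with odd-reflection padding at both ends
# to suppress edge transients (filtfilt alone starts from zero state).
zero_phase_filter <- function(bf, x, fs) {
  n <- length(x)
  npad <- min(n - 1L, max(32L, round(0.5 * fs)))
  if (npad > 0) {
    left <- 2 * x[1] - x[(npad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - npad)]
    y <- signal::filtfilt(bf, c(left, x, right))
    y[(npad + 1):(npad + n)]
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase lag),
#' the standard choice for revealing ripple-band activity in field
#' recordings without shifting event times.
#'
#' @param rec An [lfp_recording()].
#' @param low_hz,high_hz Passband edges in Hz; `0 < low < high < Nyquist`.
#' @param order Filter order before the forward-backward pass (default 4).
#' @return A filtered [lfp_recording()] of the same length and rate.
#' @export
band_pass <- function(rec, low_hz, high_hz, order = 4) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$sampling_rate_hz
  check_band(low_hz, high_hz, fs)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  y <- zero_phase_filter(bf, rec$samples, fs)
  lfp_recording(y, fs, rec$start_time_s)
}

#' Zero-phase Butterworth high-pass filter
#'
#' @param rec An [lfp_recording()].
#' @param cutoff_hz Cutoff in Hz; `0 < cutoff < Nyquist`.
#' @param order Filter order before the forward-backward pass (default 4).
#' @return A filtered [lfp_recording()]; DC is removed.
#' @export
high_pass <- function(rec, cutoff_hz, order = 4) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$sampling_rate_hz
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop(sprintf("cutoff_hz (%g): need 0 < cutoff < Nyquist (%g Hz)",
                 cutoff_hz, fs / 2), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  y <- zero_phase_filter(bf, rec$samples, fs)
  lfp_recording(y, fs, rec$start_time_s)
}

#' Sliding root-mean-square envelope
#'
#' Centered sliding-window RMS; the window shrinks at the recording
#' edges so the output has the same length as the input.
#'
#' @param rec An [lfp_recording()] (normally a band-passed trace).
#' @param window_ms Window length in milliseconds (> 0, shorter than the
#'   recording).
#' @return An [lfp_recording()] whose samples are the RMS envelope (µV).
#' @export
sliding_rms <- function(rec, window_ms) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$sampling_rate_hz
  n <- length(rec$samples)
  if (!is.finite(window_ms) || window_ms <= 0) {
    stop("window_ms: must be positive", call. = FALSE)
  }
  w <- round(window_ms / 1000 * fs)
  if (w < 1) w <- 1L
  if (w >= n) {
    stop("window_ms: window must be shorter than the recording", call. = FALSE)
  }
  half <- floor(w / 2)
  cs <- c(0, cumsum(rec$samples^2))
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  rms <- sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
  lfp_recording(rms, fs, rec$start_time_s)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' Welch power spectral density
#'
#' One-sided power spectral density by Welch's method: Hann-windowed
#' overlapping segments, averaged modified periodograms. Satisfies
#' Parseval's relation (the integral of the density approximates the
#' trace variance) for stationary inputs.
#'
#' @param rec An [lfp_recording()].
#' @param segment_s Segment length in seconds (default 2, giving 0.5 Hz
#'   resolution).
#' @param overlap_frac Fractional overlap between segments in `[0, 1)`
#'   (default 0.5).
#' @return An object of class `power_spectrum` with fields `freqs_hz`,
#'   `power` (µV²/Hz) and `resolution_hz`. The DC bin is dropped.
#' @export
welch_spectrum <- function(rec, segment_s = 2, overlap_frac = 0.5) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$sampling_rate_hz
  n <- length(rec$samples)
  nseg <- round(segment_s * fs)
  if (nseg < 16) {
    stop("segment_s: segment must span at least 16 samples", call. = FALSE)
  }
  if (n < nseg) {
    stop("recording shorter than one Welch segment", call. = FALSE)
  }
  if (!is.finite(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1) {
    stop("overlap_frac: must be in [0, 1)", call. = FALSE)
  }
  x <- rec$samples - mean(rec$samples)
  w <- hann_window(nseg)
  u <- sum(w^2)
  step <- max(1L, round(nseg * (1 - overlap_frac)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  nhalf <- floor(nseg / 2)
  acc <- numeric(nhalf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)] * w
    X <- stats::fft(seg)
    acc <- acc + Mod(X[2:(nhalf + 1)])^2
  }
  pxx <- acc / length(starts) * 2 / (fs * u)
  # Nyquist bin (present when nseg even) is not doubled
  if (nseg %% 2 == 0) pxx[nhalf] <- pxx[nhalf] / 2
  freqs <- fs * (1:nhalf) / nseg
  structure(
    list(freqs_hz = freqs, power = pxx, resolution_hz = fs / nseg),
    class = "power_spectrum"
  )
}

#' Morlet continuous wavelet transform power
#'
#' Time-frequency power by convolution with complex Morlet wavelets
#' (center frequency parameter `omega0`), computed in the frequency
#' domain. The scale-frequency relation uses the standard Fourier factor
#' `(omega0 + sqrt(2 + omega0^2)) / (4 pi)`.
#'
#' @param rec An [lfp_recording()].
#' @param freqs_hz Ascending analysis frequencies in Hz, inside
#'   `(0, Nyquist)`.
#' @param omega0 Morlet nondimensional frequency (default 6; >= 5 keeps
#'   the wavelet admissible in practice).
#' @return An object of class `tf_power` with `freqs_hz`, `times_s` and
#'   `power` (frequency x time matrix, squared modulus). Attribute
#'   `coi_s` gives the e-folding (cone-of-influence) duration per
#'   frequency; edge samples closer than `coi_s` to either end are
#'   boundary-contaminated but are not dropped.
#' @export
morlet_cwt <- function(rec, freqs_hz, omega0 = 6) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (length(freqs_hz) < 1L) stop("freqs_hz: empty frequency grid", call. = FALSE)
  fs <- rec$sampling_rate_hz
  if (any(!is.finite(freqs_hz)) || any(freqs_hz <= 0) ||
      any(freqs_hz >= fs / 2)) {
    stop("freqs_hz: frequencies must lie in (0, Nyquist)", call. = FALSE)
  }
  if (is.unsorted(freqs_hz, strictly = TRUE)) {
    stop("freqs_hz: must be strictly ascending", call. = FALSE)
  }
  x <- rec$samples - mean(rec$samples)
  n <- length(x)
  npad <- 2^ceiling(log2(max(n, 2)))
  X <- stats::fft(c(x, numeric(npad - n)))
  k <- 0:(npad - 1)
  omega <- 2 * pi * fs * ifelse(k <= npad / 2, k, k - npad) / npad
  ff <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  pow <- matrix(0, nrow = length(freqs_hz), ncol = n)
  for (i in seq_along(freqs_hz)) {
    s <- ff / freqs_hz[i]
    psi_hat <- pi^(-0.25) * sqrt(2 * pi * s * fs) *
      exp(-0.5 * (s * omega - omega0)^2) * (omega > 0)
    wt <- stats::fft(X * psi_hat, inverse = TRUE) / npad
    pow[i, ] <- Mod(wt[1:n])^2
  }
  structure(
    list(freqs_hz = freqs_hz, times_s = lfp_times(rec), power = pow),
    coi_s = sqrt(2) * ff / freqs_hz,
    class = "tf_power"
  )
}
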