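# Independent oracles used across tests.

make_tone <- function(freq_hz, fs = 2000, duration_s = 2, amplitude = 1,
                      phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  lfp_recording(amplitude * sin(2 * pi * freq_hz * t + phase), fs)
}

# All-pairs Mann-Whitney AUC with ties counted 1/2.
oracle_auc <- function(values, labels, positive = "case",
                       direction = "high_is_positive") {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  win <- if (direction == "high_is_positive") outer(pos, neg, ">") else
    outer(pos, neg, "<")
  (sum(win) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Exhaustive Youden scan over all midpoint cutoffs, with the package's
# declared tie-breaks (higher accuracy, then lower cutoff) re-derived
# independently.
oracle_youden <- function(values, labels, positive = "case",
                          direction = "high_is_positive") {
  v <- sort(unique(values))
  thr <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  best <- NULL
  for (c0 in thr) {
    if (direction == "high_is_positive") {
      se <- mean(pos >= c0); sp <- mean(neg < c0)
    } else {
      se <- mean(pos <= c0); sp <- mean(neg > c0)
    }
    j <- se + sp - 1
    acc <- (se * length(pos) + sp * length(neg)) / length(values)
    better <- is.null(best) || j > best$j + 1e-12 ||
      (abs(j - best$j) <= 1e-12 && acc > best$acc + 1e-12) ||
      (abs(j - best$j) <= 1e-12 && abs(acc - best$acc) <= 1e-12 &&
         c0 < best$cutoff)
    if (better) best <- list(cutoff = c0, j = j, acc = acc)
  }
  best
}

# Direct time-domain Morlet convolution at one frequency and selected
# sample indices (input should already be demeaned).
oracle_morlet_power <- function(x, fs, freq_hz, omega0 = 6, idx) {
  ff <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  s <- ff / freq_hz
  t <- (seq_along(x) - 1) / fs
  vapply(idx, function(n0) {
    dtau <- t - t[n0]
    w <- sum(x * pi^(-0.25) * exp(-dtau^2 / (2 * s^2)) *
               exp(-1i * omega0 * dtau / s)) / sqrt(s * fs)
    Mod(w)^2
  }, numeric(1))
}

# Analytic analog-prototype Butterworth magnitudes (single pass); the
# zero-phase filter squares these. Close to the digital filter well
# below Nyquist, which is where the assertions sit.
butter_bandpass_mag <- function(f, low, high, order = 4) {
  om <- (f^2 - low * high) / (f * (high - low))
  1 / sqrt(1 + om^(2 * order))
}
butter_highpass_mag <- function(f, cutoff, order = 4) {
  1 / sqrt(1 + (cutoff / f)^(2 * order))
}
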